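#' Dual regression stage A: subject time courses
#'
#' Regresses each volume's voxel vector on the K group spatial maps
#' (maps demeaned over voxels, data demeaned per voxel over time), yielding
#' one time course per component; each time course is then demeaned and
#' variance-normalized to unit sample SD.
#'
#' @param run a [bold_run()].
#' @param group_maps K x voxels matrix of group spatial maps (e.g.,
#'   `spatial_maps` of an [fit_group_ica()] decomposition).
#' @param voxel_index indices into the flattened grid giving the map voxel
#'   set (default: the run's `voxel_index` attribute, else all voxels).
#' @return A `subject_timecourses`: `values` (timepoints x K, unit
#'   variance), `subject_id`.
#' @export
stage_a <- function(run, group_maps, voxel_index = NULL) {
  stopifnot(inherits(run, "bold_run"))
  voxel_index <- voxel_index %||% attr(run, "voxel_index") %||%
    seq_len(prod(grid_shape(run)))
  G <- t(group_maps)                       # V x K
  if (nrow(G) != length(voxel_index)) stop("map voxel set does not match run")
  K <- ncol(G)
  if (K >= n_volumes(run)) stop("need fewer components than timepoints")
  G <- sweep(G, 2, colMeans(G))            # demean maps over voxels
  qrG <- qr(G)
  if (qrG$rank < K) {
    cm <- abs(stats::cor(G))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    stop(sprintf("rank-deficient group maps (components %d and %d are collinear)",
                 worst[1], worst[2]))
  }
  Y <- t(run_matrix(run)[voxel_index, , drop = FALSE])   # T x V
  Y <- sweep(Y, 2, colMeans(Y))            # demean data per voxel over time
  TC <- t(qr.coef(qrG, t(Y)))              # T x K
  TC <- sweep(TC, 2, colMeans(TC))
  sdv <- sqrt(colSums(TC^2) / (nrow(TC) - 1))
  if (any(sdv < 1e-12)) stop("degenerate (constant) recovered time course")
  TC <- sweep(TC, 2, sdv, "/")
  structure(list(values = TC, subject_id = run$subject_id),
            class = "subject_timecourses")
}

#' Dual regression stage B: subject spatial maps
#'
#' Regresses each voxel's time series on the K normalized subject time
#' courses; the regression coefficients form the subject-specific spatial
#' maps.
#'
#' @param run a [bold_run()].
#' @param tcs a `subject_timecourses` from [stage_a()].
#' @param voxel_index as in [stage_a()].
#' @return A `subject_spatial_map`: `values` (K x voxels), `subject_id`.
#' @export
stage_b <- function(run, tcs, voxel_index = NULL) {
  stopifnot(inherits(run, "bold_run"), inherits(tcs, "subject_timecourses"))
  voxel_index <- voxel_index %||% attr(run, "voxel_index") %||%
    seq_len(prod(grid_shape(run)))
  D <- tcs$values                          # T x K
  if (nrow(D) != n_volumes(run)) stop("time course length does not match run")
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("rank-deficient time-course matrix")
  Y <- t(run_matrix(run)[voxel_index, , drop = FALSE])   # T x V
  Y <- sweep(Y, 2, colMeans(Y))
  B <- qr.coef(qrD, Y)                     # K x V
  if (!all(is.finite(B))) stop("non-finite stage-B coefficients")
  structure(list(values = B, subject_id = tcs$subject_id),
            class = "subject_spatial_map")
}

#' Run both dual-regression stages for every subject
#'
#' @param runs list of [bold_run()] sharing the decomposition's voxel set.
#' @param decomp an `ica_decomposition` (or a K x voxels map matrix).
#' @param voxel_index voxel set (default from the decomposition).
#' @return list with `timecourses` and `maps` (named per subject).
#' @export
dual_regression <- function(runs, decomp, voxel_index = NULL) {
  if (inherits(decomp, "ica_decomposition")) {
    maps <- decomp$spatial_maps
    voxel_index <- voxel_index %||% decomp$voxel_index
  } else {
    maps <- decomp
  }
  tcs <- lapply(runs, stage_a, group_maps = maps, voxel_index = voxel_index)
  sm <- mapply(stage_b, runs, tcs, MoreArgs = list(voxel_index = voxel_index),
               SIMPLIFY = FALSE)
  names(tcs) <- names(sm) <- vapply(runs, `[[`, "", "subject_id")
  list(timecourses = tcs, maps = sm)
}

# pooled-variance two-sample t per voxel; x1, x2 are subjects x voxels
two_sample_t <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  ss1 <- colSums(x1^2) - n1 * m1^2
  ss2 <- colSums(x2^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[!is.finite(t)] <- 0
  t
}

#' Voxelwise two-group permutation test with max-statistic FWE control
#'
#' Computes the observed pooled-variance two-sample t per voxel, builds the
#' null by permuting group labels (exhaustively when the number of
#' assignments fits within `n_perm`, randomly otherwise) and records the
#' maximum |t| over voxels per permutation. The family-wise-corrected
#' p-value is `(1 + #permutation maxima >= |t_obs|) / (n_perm + 1)` for
#' random permutations, and the exact tail proportion under exhaustive
#' enumeration; ties count against significance.
#'
#' @param maps_group1,maps_group2 subjects x voxels matrices of
#'   subject-specific maps for one component (each group >= 2 subjects).
#' @param n_perm permutation budget (default 10000; < 100 warns).
#' @param seed RNG seed for random permutations.
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; `NULL` auto-selects.
#' @return A `group_stat_map`: `tmap`, `p_fwe`, `n_permutations`,
#'   `exhaustive`, `contrast` (`"group1-group2"`, two-sided inference).
#' @export
permutation_group_test <- function(maps_group1, maps_group2, n_perm = 10000,
                                   seed = 0, exhaustive = NULL) {
  x1 <- as.matrix(maps_group1); x2 <- as.matrix(maps_group2)
  if (nrow(x1) < 2 || nrow(x2) < 2) stop("each group needs >= 2 subjects")
  if (ncol(x1) != ncol(x2)) stop("voxel sets differ between groups")
  if (n_perm < 100) warning("n_perm < 100 gives very coarse p-values")
  n1 <- nrow(x1); n <- n1 + nrow(x2)
  pooled <- rbind(x1, x2)
  # t is invariant to per-voxel shifts; centering improves the numerical
  # stability of the sum-of-squares form used in the permutation loop
  pooled <- sweep(pooled, 2, colMeans(pooled))
  t_obs <- two_sample_t(pooled[seq_len(n1), , drop = FALSE],
                        pooled[-seq_len(n1), , drop = FALSE])
  n_assign <- choose(n, n1)
  use_exh <- exhaustive %||% (n_assign <= n_perm)
  if (use_exh) {
    combs <- utils::combn(n, n1)
    maxstat <- apply(combs, 2, function(ix) {
      max(abs(two_sample_t(pooled[ix, , drop = FALSE],
                           pooled[-ix, , drop = FALSE])))
    })
    p <- vapply(abs(t_obs), function(t0) mean(maxstat >= t0), numeric(1))
    n_eff <- ncol(combs)
  } else {
    maxstat <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      ix <- sample.int(n, n1)
      max(abs(two_sample_t(pooled[ix, , drop = FALSE],
                           pooled[-ix, , drop = FALSE])))
    }, numeric(1)))
    p <- vapply(abs(t_obs), function(t0) {
      (1 + sum(maxstat >= t0)) / (n_perm + 1)
    }, numeric(1))
    n_eff <- n_perm
  }
  structure(list(tmap = t_obs, p_fwe = p, n_permutations = n_eff,
                 exhaustive = use_exh, contrast = "group1-group2",
                 seed = seed),
            class = "group_stat_map")
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat(sprintf("<group_stat_map> %d voxels, %d %s permutations, min p_fwe %.4g, %d voxels with p<0.05\n",
              length(x$tmap), x$n_permutations,
              if (x$exhaustive) "exhaustive" else "random",
              min(x$p_fwe), sum(x$p_fwe < 0.05)))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)` — used when one network is represented by
#' several (duplicate) components, each tested separately.
#'
#' @param p_values numeric p-values.
#' @param m number of comparisons (`>= length(p_values)`, `>= 1`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m) {
  if (m < 1) stop("'m' must be >= 1")
  if (m < length(p_values)) stop("'m' must be at least the number of tests")
  pmin(1, p_values * m)
}

#' Summarize a significant difference map
#'
#' Over voxels with `p_fwe < alpha`: voxel count, physical volume, peak
#' (max |t|) voxel coordinates, and the mean/SD/min/max of the t-scores.
#'
#' @param stat a `group_stat_map`.
#' @param alpha significance level (default 0.05).
#' @param voxel_index,grid_shape optional mapping of the stat voxels to a 3D
#'   grid for peak coordinates (voxel indices).
#' @param voxel_volume_mm3 volume of one voxel (default 64, i.e. 4 mm
#'   isotropic).
#' @return one-row data.frame: `n_voxels`, `volume_mm3`, `peak_x/y/z`,
#'   `t_mean`, `t_sd`, `t_min`, `t_max` (NA when no voxel is significant).
#' @export
difference_map_stats <- function(stat, alpha = 0.05, voxel_index = NULL,
                                 grid_shape = NULL, voxel_volume_mm3 = 64) {
  stopifnot(inherits(stat, "group_stat_map"))
  sig <- which(stat$p_fwe < alpha)
  if (length(sig) == 0L) {
    return(data.frame(n_voxels = 0L, volume_mm3 = 0,
                      peak_x = NA_integer_, peak_y = NA_integer_,
                      peak_z = NA_integer_, t_mean = NA_real_, t_sd = NA_real_,
                      t_min = NA_real_, t_max = NA_real_))
  }
  ts <- stat$tmap[sig]
  peak <- sig[which.max(abs(ts))]
  pk <- c(NA_integer_, NA_integer_, NA_integer_)
  if (!is.null(voxel_index) && !is.null(grid_shape)) {
    pk <- arrayInd(voxel_index[peak], grid_shape)[1, ]
  }
  data.frame(n_voxels = length(sig),
             volume_mm3 = length(sig) * voxel_volume_mm3,
             peak_x = pk[1], peak_y = pk[2], peak_z = pk[3],
             t_mean = mean(ts), t_sd = if (length(ts) > 1) stats::sd(ts) else 0,
             t_min = min(ts), t_max = max(ts))
}
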