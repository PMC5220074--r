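#' Voxelwise coefficient-of-variation map
#'
#' For each voxel the CV is the sample standard deviation (divisor t-1) of
#' the time series divided by its temporal mean. Voxels whose mean falls
#' below `mean_floor` (background, air) are set to 0 and marked invalid
#' rather than dividing by a vanishing mean.
#'
#' @param run a [bold_run()] with at least 2 volumes.
#' @param mean_floor positive floor on the temporal mean, in signal units.
#'   Default `1e-6 * median(|data|)` of this run (falls back to 1e-6 when the
#'   median is zero).
#' @return A `cv_map`: list with `values` (3D array, dimensionless) and
#'   `valid_mask` (3D logical).
#' @export
compute_cv_map <- function(run, mean_floor = NULL) {
  stopifnot(inherits(run, "bold_run"))
  if (n_volumes(run) < 2L) stop("CV needs at least 2 volumes")
  X <- run_matrix(run)
  if (is.null(mean_floor)) mean_floor <- default_floor(X)
  if (mean_floor <= 0) stop("'mean_floor' must be positive")
  m <- rowMeans(X)
  s <- row_sd(X)
  valid <- m >= mean_floor
  cv <- numeric(length(m))
  cv[valid] <- s[valid] / m[valid]
  structure(list(values = array(cv, grid_shape(run)),
                 valid_mask = array(valid, grid_shape(run)),
                 subject_id = run$subject_id),
            class = "cv_map")
}

#' Voxelwise temporal signal-to-noise ratio map
#'
#' tSNR = temporal mean / sample SD per voxel — the reciprocal of the CV.
#' Voxels whose SD falls below `sd_floor` (e.g., constant series) are marked
#' invalid instead of producing infinities.
#'
#' @param run a [bold_run()].
#' @param sd_floor positive floor on the temporal SD, in signal units;
#'   default as in [compute_cv_map()].
#' @return A `tsnr_map`: `values` (3D) and `valid_mask` (3D logical).
#' @export
compute_tsnr_map <- function(run, sd_floor = NULL) {
  stopifnot(inherits(run, "bold_run"))
  if (n_volumes(run) < 2L) stop("tSNR needs at least 2 volumes")
  X <- run_matrix(run)
  if (is.null(sd_floor)) sd_floor <- default_floor(X)
  if (sd_floor <= 0) stop("'sd_floor' must be positive")
  m <- rowMeans(X)
  s <- row_sd(X)
  valid <- s >= sd_floor
  tsnr <- numeric(length(m))
  tsnr[valid] <- m[valid] / s[valid]
  structure(list(values = array(tsnr, grid_shape(run)),
                 valid_mask = array(valid, grid_shape(run)),
                 subject_id = run$subject_id),
            class = "tsnr_map")
}

default_floor <- function(X) {
  med <- stats::median(abs(X))
  if (med <= 0) 1e-6 else 1e-6 * med
}

#' @export
print.cv_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("<cv_map> %s: %d valid voxels, median CV %.4g\n",
              x$subject_id %||% "?", sum(x$valid_mask), stats::median(v)))
  invisible(x)
}

#' @export
print.tsnr_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("<tsnr_map> %s: %d valid voxels, median tSNR %.4g\n",
              x$subject_id %||% "?", sum(x$valid_mask), stats::median(v)))
  invisible(x)
}

#' Mean tSNR within a brain mask
#'
#' Arithmetic mean of the tSNR over the intersection of `brain_mask` with
#' the map's valid mask.
#'
#' @param map a `tsnr_map`.
#' @param brain_mask 3D logical array on the same grid.
#' @return scalar mean tSNR.
#' @export
mean_tsnr <- function(map, brain_mask) {
  stopifnot(inherits(map, "tsnr_map"))
  if (!all(dim(brain_mask) == dim(map$values))) stop("grid mismatch")
  sel <- brain_mask & map$valid_mask
  if (!any(sel)) stop("brain mask does not overlap the valid tSNR voxels")
  mean(map$values[sel])
}

# crude data-driven brain mask: voxels whose temporal mean exceeds a fraction
# of the maximal mean (phantom air is ~0, tissue ~baseline)
brain_mask_from_run <- function(run, frac = 0.2) {
  m <- rowMeans(run_matrix(run))
  array(m > frac * max(m), grid_shape(run))
}

#' Build a normative CV reference from a healthy cohort
#'
#' Voxelwise mean and sample SD (divisor n-1) of the per-subject CV maps;
#' the reference valid mask is the intersection of the subjects' valid
#' masks.
#'
#' @param cv_maps list of `cv_map` objects on one grid (>= 2).
#' @return A `normative_reference`: `mean_cv`, `sd_cv` (3D arrays),
#'   `n_subjects`, `valid_mask`.
#' @export
build_normative_reference <- function(cv_maps) {
  if (length(cv_maps) < 2L) stop("need at least 2 CV maps")
  dims <- dim(cv_maps[[1]]$values)
  for (m in cv_maps) {
    if (!all(dim(m$values) == dims)) stop("CV map grid mismatch")
  }
  stack <- vapply(cv_maps, function(m) as.numeric(m$values),
                  numeric(prod(dims)))
  valid <- Reduce(`&`, lapply(cv_maps, `[[`, "valid_mask"))
  mu <- rowMeans(stack)
  sdv <- sqrt(rowSums((stack - mu)^2) / (length(cv_maps) - 1))
  mu[!valid] <- 0
  sdv[!valid] <- 0
  structure(list(mean_cv = array(mu, dims), sd_cv = array(sdv, dims),
                 n_subjects = length(cv_maps), valid_mask = array(valid, dims)),
            class = "normative_reference")
}

#' @export
print.normative_reference <- function(x, ...) {
  cat(sprintf("<normative_reference> n=%d, %d valid voxels, mean CV %.4g\n",
              x$n_subjects, sum(x$valid_mask),
              mean(x$mean_cv[x$valid_mask])))
  invisible(x)
}

#' Deviation z-map of a subject CV map against the normative reference
#'
#' `z = (cv - mean_cv) / max(sd_cv, sd_floor)` on the joint valid mask, 0
#' elsewhere.
#'
#' @param cv a `cv_map`.
#' @param ref a `normative_reference` on the same grid.
#' @param sd_floor dimensionless floor on the reference SD (guards the
#'   noise-free limit where the normative SD vanishes).
#' @return A `deviation_zmap`: `values` (3D z array) and `valid_mask`.
#' @export
deviation_zmap <- function(cv, ref, sd_floor = 1e-6) {
  stopifnot(inherits(cv, "cv_map"), inherits(ref, "normative_reference"))
  if (!all(dim(cv$values) == dim(ref$mean_cv))) stop("grid mismatch")
  valid <- cv$valid_mask & ref$valid_mask
  z <- array(0, dim(cv$values))
  denom <- pmax(ref$sd_cv[valid], sd_floor)
  z[valid] <- (cv$values[valid] - ref$mean_cv[valid]) / denom
  structure(list(values = z, valid_mask = valid,
                 subject_id = cv$subject_id), class = "deviation_zmap")
}

zmap_parts <- function(zmap) {
  if (inherits(zmap, "deviation_zmap")) {
    list(z = zmap$values, valid = zmap$valid_mask)
  } else {
    list(z = zmap, valid = array(TRUE, dim(zmap)))
  }
}

#' Stripe score of a deviation z-map
#'
#' Mean |z| is computed per slice (3rd axis) over valid voxels; the score is
#' the maximum slice mean minus the median slice mean. Slice-localized
#' deviations score high; a uniform global z offset scores 0.
#'
#' @param zmap a `deviation_zmap` (or plain 3D z array).
#' @return scalar stripe score.
#' @export
stripe_score <- function(zmap) {
  p <- zmap_parts(zmap)
  nz <- dim(p$z)[3]
  slice_means <- vapply(seq_len(nz), function(k) {
    v <- p$valid[, , k]
    if (!any(v)) NA_real_ else mean(abs(p$z[, , k][v]))
  }, numeric(1))
  slice_means <- slice_means[is.finite(slice_means)]
  if (length(slice_means) < 3L) stop("stripe score needs at least 3 slices with valid voxels")
  max(slice_means) - stats::median(slice_means)
}

#' Widespread-defect score of a deviation z-map
#'
#' Fraction of valid voxels with |z| above `z_thresh`; high for globally
#' deviant (widespread signal defect) runs.
#'
#' @param zmap a `deviation_zmap` (or plain 3D z array).
#' @param z_thresh absolute z threshold (default 3).
#' @return scalar in \[0, 1\].
#' @export
defect_score <- function(zmap, z_thresh = 3) {
  p <- zmap_parts(zmap)
  if (!any(p$valid)) stop("defect score undefined on an empty valid mask")
  mean(abs(p$z[p$valid]) > z_thresh)
}

#' Score every run of a cohort against a normative reference
#'
#' Computes per run: CV map, deviation z-map, stripe and defect scores, and
#' mean tSNR in a brain mask.
#'
#' @param runs named list of [bold_run()] (ideally preprocessed the same way
#'   as the normative cohort).
#' @param ref a `normative_reference`.
#' @param brain_mask 3D logical; default a data-driven mask from each run.
#' @return data.frame with one row per run: `subject_id`, `group`,
#'   `mean_tsnr`, `stripe_score`, `defect_score`.
#' @export
score_runs <- function(runs, ref, brain_mask = NULL) {
  rows <- lapply(runs, function(run) {
    cv <- compute_cv_map(run)
    z <- deviation_zmap(cv, ref)
    bm <- brain_mask %||% brain_mask_from_run(run)
    data.frame(subject_id = run$subject_id, group = run$group,
               mean_tsnr = mean_tsnr(compute_tsnr_map(run), bm),
               stripe_score = stripe_score(z),
               defect_score = defect_score(z),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Data-driven flagging thresholds from a normative score distribution
#'
#' `median + 5 * MAD` of each score over the normative cohort, floored at an
#' absolute minimum per score. The floors encode what "clear aberration"
#' means on each scale regardless of how tight the healthy score spread is:
#' a stripe must lift its slice's mean |z| a full unit above the median
#' slice, and a widespread defect must put at least 15% of valid voxels
#' beyond |z| = 3. Both sit far above what noise (~0.3% of voxels beyond
#' |z| = 3) or genuine disease-related signal differences (reduced network
#' fluctuations, atrophy-driven partial-volume change) produce, while true
#' technical artifacts exceed them severalfold — flagging targets technical
#' aberration, not biology.
#'
#' @param norm_scores data.frame from [score_runs()] on the normative cohort
#'   scored against its own reference.
#' @param k multiplier on the MAD (default 5).
#' @param floors named minimal thresholds.
#' @return list with `stripe` and `defect` thresholds.
#' @export
qc_thresholds <- function(norm_scores, k = 5,
                          floors = c(stripe = 1.0, defect = 0.15)) {
  thr <- function(x, f) max(stats::median(x) + k * stats::mad(x), f)
  list(stripe = thr(norm_scores$stripe_score, floors[["stripe"]]),
       defect = thr(norm_scores$defect_score, floors[["defect"]]))
}

#' Flag artifactual runs
#'
#' A run is flagged iff its stripe score or defect score exceeds its
#' threshold; the report carries a machine-readable reason per flag.
#'
#' @param scores data.frame from [score_runs()].
#' @param thresholds list with `stripe` and `defect` (use `Inf` to disable a
#'   criterion).
#' @return A `qc_report`: the scores data.frame with `flag` (logical) and
#'   `reason` columns, thresholds attached as an attribute.
#' @export
flag_runs <- function(scores, thresholds) {
  need <- c("subject_id", "stripe_score", "defect_score")
  if (!all(need %in% names(scores)) || anyNA(scores[need])) {
    stop("scores must contain complete ", paste(need, collapse = ", "))
  }
  if (!all(c("stripe", "defect") %in% names(thresholds))) {
    stop("thresholds must name 'stripe' and 'defect'")
  }
  s_hit <- scores$stripe_score > thresholds$stripe
  d_hit <- scores$defect_score > thresholds$defect
  scores$flag <- s_hit | d_hit
  scores$reason <- ifelse(s_hit & d_hit, "cv_stripe+cv_defect",
                          ifelse(s_hit, "cv_stripe",
                                 ifelse(d_hit, "cv_defect", "")))
  structure(scores, class = c("qc_report", "data.frame"),
            thresholds = thresholds)
}

#' @export
print.qc_report <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat(sprintf("<qc_report> %d runs, %d flagged (stripe > %.3g, defect > %.3g)\n",
              nrow(x), sum(x$flag), thr$stripe, thr$defect))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write a QC report as a tab-separated table
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Mann-Whitney U test (exact for small samples)
#'
#' U is computed for `sample_a` relative to `sample_b` (number of pairs
#' where a > b, ties counting 1/2). For combined n <= 12 the two-sided p is
#' obtained by exhaustive enumeration of all group assignments of the pooled
#' values (ties handled exactly); otherwise the normal approximation with
#' tie correction is used. Identical pooled values give p = 1 by convention.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return list with `U` and `p` (two-sided).
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  u_stat <- function(idx1) {
    r <- rank(pooled)
    sum(r[idx1]) - length(idx1) * (length(idx1) + 1) / 2
  }
  U <- u_stat(seq_len(n1))
  if (length(unique(pooled)) == 1L) return(list(U = U, p = 1))
  if (n <= 12L) {
    combs <- utils::combn(n, n1)
    r <- rank(pooled)
    Us <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    lo <- min(U, n1 * n2 - U)
    hi <- n1 * n2 - lo
    p <- min(1, mean(Us <= lo | Us >= hi))
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p)
}
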