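#' Temporally concatenate runs into a group data matrix
#'
#' Each subject's voxel time series are demeaned and variance-normalized
#' (unit sample SD; voxels with vanishing within-subject variance are left
#' at zero) and the subjects are stacked along time — the multisession
#' temporal-concatenation layout for group spatial ICA.
#'
#' @param runs list of [bold_run()] on one grid.
#' @param voxel_index integer indices into the flattened grid giving the
#'   shared voxel set. Default: the `voxel_index` attribute of the runs
#'   (set by [apply_gm_mask()]), which must then agree across runs; if
#'   absent, all voxels.
#' @return A `bold_matrix`: `values` (total timepoints x voxels),
#'   `subject_boundaries` (list of row ranges), `subject_ids`, `groups`,
#'   `voxel_index`, `grid_shape`, `tr_seconds`.
#' @export
concatenate_runs <- function(runs, voxel_index = NULL) {
  stopifnot(length(runs) >= 1L)
  g <- grid_shape(runs[[1]])
  for (r in runs) if (!all(grid_shape(r) == g)) stop("grid mismatch across runs")
  if (is.null(voxel_index)) {
    vi <- lapply(runs, attr, "voxel_index")
    if (!is.null(vi[[1]])) {
      for (v in vi) {
        if (is.null(v) || !identical(v, vi[[1]])) {
          stop("runs carry differing voxel sets; pass 'voxel_index' explicitly")
        }
      }
      voxel_index <- vi[[1]]
    } else {
      voxel_index <- seq_len(prod(g))
    }
  }
  blocks <- vector("list", length(runs))
  bounds <- vector("list", length(runs))
  row0 <- 0L
  for (s in seq_along(runs)) {
    X <- t(run_matrix(runs[[s]])[voxel_index, , drop = FALSE])  # T x V
    mu <- colMeans(X)
    X <- sweep(X, 2, mu)
    sdv <- sqrt(colSums(X^2) / (nrow(X) - 1))
    pos <- sdv > 1e-12
    X[, pos] <- sweep(X[, pos, drop = FALSE], 2, sdv[pos], "/")
    X[, !pos] <- 0
    blocks[[s]] <- X
    bounds[[s]] <- c(row0 + 1L, row0 + nrow(X))
    row0 <- row0 + nrow(X)
  }
  structure(list(values = do.call(rbind, blocks),
                 subject_boundaries = bounds,
                 subject_ids = vapply(runs, `[[`, "", "subject_id"),
                 groups = vapply(runs, `[[`, "", "group"),
                 voxel_index = voxel_index, grid_shape = g,
                 tr_seconds = runs[[1]]$tr_seconds),
            class = "bold_matrix")
}

#' @export
print.bold_matrix <- function(x, ...) {
  cat(sprintf("<bold_matrix> %d rows (%d subjects) x %d voxels\n",
              nrow(x$values), length(x$subject_boundaries), ncol(x$values)))
  invisible(x)
}

sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  if (any(e$values <= 1e-12)) stop("degenerate unmixing matrix")
  solve_sqrt <- e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*% t(e$vectors)
  solve_sqrt %*% W
}

#' Fit a group spatial ICA
#'
#' Reduces the concatenated data to `k` dimensions by principal components,
#' then rotates the whitened spatial principal components to maximal
#' non-Gaussianity of the voxelwise source distributions (log-cosh contrast,
#' symmetric decorrelation — the fastICA fixed point). Each spatial map is
#' z-scored over voxels and its sign fixed so the map skewness is
#' non-negative, making the fit reproducible.
#'
#' @param dm a `bold_matrix` from [concatenate_runs()].
#' @param k number of components (`1 <= k <= rank`).
#' @param seed RNG seed for the unmixing initialization.
#' @param maxit,tol fixed-point iteration controls.
#' @return An `ica_decomposition`: `spatial_maps` (k x voxels, z-scored),
#'   `mixing` (total timepoints x k), `k`, `seed`, `iterations`, plus the
#'   matrix's voxel/subject bookkeeping.
#' @export
fit_group_ica <- function(dm, k, seed = 0, maxit = 1000, tol = 1e-6) {
  stopifnot(inherits(dm, "bold_matrix"))
  X <- dm$values
  # data conditioning: remove each volume's grand mean over voxels, so the
  # principal subspace is orthogonal to the constant map and z-scoring the
  # source maps is a pure rescaling (reconstruction identity preserved)
  X <- X - rowMeans(X)
  n <- nrow(X); V <- ncol(X)
  if (k < 1 || k > min(n, V)) stop("'k' must be in [1, min(timepoints, voxels)]")
  # PCA via the smaller Gram matrix
  if (n <= V) {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    if (d[k] < 1e-8 * d[1]) stop("'k' exceeds the numerical rank of the data")
    U <- e$vectors[, seq_len(k), drop = FALSE]
    Vt <- diag(1 / d[seq_len(k)], k) %*% t(U) %*% X      # k x V, orthonormal rows
  } else {
    e <- eigen(crossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    if (d[k] < 1e-8 * d[1]) stop("'k' exceeds the numerical rank of the data")
    Vt <- t(e$vectors[, seq_len(k), drop = FALSE])
  }
  Z <- sqrt(V) * Vt                                      # whitened: Z Z' / V = I
  iterations <- 0L
  if (k == 1L) {
    W <- matrix(1, 1, 1)
  } else {
    W <- with_seed(seed, matrix(stats::rnorm(k * k), k, k))
    W <- sym_decorrelate(W)
    repeat {
      iterations <- iterations + 1L
      S <- W %*% Z
      G <- tanh(S)
      W1 <- G %*% t(Z) / V - diag(rowMeans(1 - G^2), k) %*% W
      W1 <- sym_decorrelate(W1)
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) break
      if (iterations >= maxit) {
        stop("group ICA did not converge within ", maxit, " iterations")
      }
    }
  }
  S <- W %*% Z
  # z-score maps over voxels and fix the sign by skewness
  for (i in seq_len(k)) {
    s <- S[i, ]
    s <- (s - mean(s)) / stats::sd(s)
    if (skewness(s) < 0) s <- -s
    S[i, ] <- s
  }
  A <- X %*% t(S) %*% solve(tcrossprod(S))
  structure(list(spatial_maps = S, mixing = A, k = k, seed = seed,
                 iterations = iterations,
                 voxel_index = dm$voxel_index, grid_shape = dm$grid_shape,
                 subject_boundaries = dm$subject_boundaries,
                 subject_ids = dm$subject_ids, groups = dm$groups,
                 tr_seconds = dm$tr_seconds, thresholds = NULL),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> k=%d over %d voxels, %d subjects (seed %s, %d iterations)\n",
              x$k, ncol(x$spatial_maps), length(x$subject_boundaries),
              format(x$seed), x$iterations))
  invisible(x)
}

#' @export
summary.ica_decomposition <- function(object, ...) {
  sk <- apply(object$spatial_maps, 1, skewness)
  tab <- data.frame(component = seq_len(object$k),
                    skewness = sk,
                    max_abs_z = apply(abs(object$spatial_maps), 1, max))
  cat(sprintf("Group spatial ICA: %d components, %d voxels, %d concatenated timepoints\n",
              object$k, ncol(object$spatial_maps), nrow(object$mixing)))
  print(tab, digits = 3, row.names = FALSE)
  invisible(tab)
}

#' Re-project a component map onto the 3D grid
#'
#' @param decomp an `ica_decomposition`.
#' @param component component index.
#' @return 3D array (zeros off the voxel set).
#' @export
map_to_3d <- function(decomp, component) {
  arr <- array(0, decomp$grid_shape)
  arr[decomp$voxel_index] <- decomp$spatial_maps[component, ]
  arr
}

#' Threshold a z-scored spatial map by a Gaussian/gamma mixture
#'
#' Fits, by EM, a central Gaussian (background) plus a positive-tail gamma
#' (activation; optionally also a negative-tail gamma) to the voxel
#' intensity distribution, and keeps a voxel as active when its posterior
#' probability of the activation class exceeds 0.5 — false positives and
#' false negatives weighted equally. On EM failure the map falls back to a
#' fixed |z| > 2.3 threshold with a warning.
#'
#' @param map numeric vector of map intensities (>= 100 voxels).
#' @param three_class also model a negative gamma tail.
#' @param maxit,tol EM controls.
#' @return list with `active` (logical vector), `params` (mixture fit),
#'   `method` (`"mixture"` or `"fallback"`).
#' @export
threshold_map <- function(map, three_class = FALSE, maxit = 500, tol = 1e-6) {
  x <- as.numeric(map)
  if (length(x) < 100L) stop("mixture thresholding needs >= 100 voxels")
  if (stats::sd(x) < .Machine$double.eps) {
    stop("constant map: no intensity distribution to fit")
  }
  fit <- tryCatch(ggmix_em(x, three_class, maxit, tol), error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian/gamma EM did not converge; falling back to |z| > 2.3")
    return(list(active = abs(x) > 2.3, params = NULL, method = "fallback"))
  }
  list(active = fit$post_act > 0.5, params = fit$params, method = "mixture")
}

# EM for pi0*N(mu,sd) + pi1*Gamma(shape,rate) on x>0 (+ optional negative
# gamma on -x). Gamma parameters by weighted moment matching.
ggmix_em <- function(x, three_class, maxit, tol) {
  n <- length(x)
  mu <- stats::median(x); sdv <- stats::mad(x)
  if (sdv <= 0) sdv <- stats::sd(x)
  q99 <- stats::quantile(x, 0.99)
  gam <- list(shape = 3, rate = 3 / max(q99, 0.5))
  gneg <- list(shape = 3, rate = 3 / max(abs(stats::quantile(x, 0.01)), 0.5))
  pis <- if (three_class) c(0.9, 0.05, 0.05) else c(0.95, 0.05)
  eps <- 1e-300
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    d0 <- stats::dnorm(x, mu, sdv)
    d1 <- ifelse(x > 0, stats::dgamma(x, gam$shape, gam$rate), 0)
    dens <- cbind(pis[1] * d0, pis[2] * d1)
    if (three_class) {
      d2 <- ifelse(x < 0, stats::dgamma(-x, gneg$shape, gneg$rate), 0)
      dens <- cbind(dens, pis[3] * d2)
    }
    tot <- rowSums(dens) + eps
    r <- dens / tot
    ll <- sum(log(tot))
    pis <- pmax(colMeans(r), 1e-6)
    pis <- pis / sum(pis)
    w0 <- r[, 1]
    mu <- sum(w0 * x) / sum(w0)
    sdv <- sqrt(sum(w0 * (x - mu)^2) / sum(w0))
    if (!is.finite(sdv) || sdv < 1e-8) stop("background class collapsed")
    w1 <- r[, 2]
    if (sum(w1) > 1e-8) {
      m1 <- sum(w1 * pmax(x, 0)) / sum(w1)
      v1 <- sum(w1 * (pmax(x, 0) - m1)^2) / sum(w1)
      if (m1 > 0 && v1 > 1e-10) {
        gam <- list(shape = m1^2 / v1, rate = m1 / v1)
      }
    }
    if (three_class && sum(r[, 3]) > 1e-8) {
      w2 <- r[, 3]
      m2 <- sum(w2 * pmax(-x, 0)) / sum(w2)
      v2 <- sum(w2 * (pmax(-x, 0) - m2)^2) / sum(w2)
      if (m2 > 0 && v2 > 1e-10) gneg <- list(shape = m2^2 / v2, rate = m2 / v2)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
    if (it == maxit) stop("EM reached maxit without converging")
  }
  list(post_act = r[, 2],
       params = list(pi = pis, mu = mu, sd = sdv, gamma = gam,
                     gamma_neg = if (three_class) gneg else NULL,
                     loglik = ll, iterations = it))
}

#' Match components to network templates
#'
#' For each named template the component with maximal spatial Pearson
#' correlation is reported (ties broken by the lower component index);
#' matches below `r_min` are reported as unmatched. All components at or
#' above `r_min` are retained as candidates (the Bonferroni set for
#' duplicate networks).
#'
#' @param decomp an `ica_decomposition`.
#' @param templates named list of 3D arrays (or vectors over the
#'   decomposition's voxel set).
#' @param r_min minimal correlation for a match (default 0.2).
#' @return data.frame (`template`, `component`, `r`, `matched`) with
#'   attribute `candidates`: per template, the indices of all components
#'   with `r >= r_min`.
#' @export
match_rsn <- function(decomp, templates, r_min = 0.2) {
  stopifnot(inherits(decomp, "ica_decomposition"), length(templates) >= 1L)
  vi <- decomp$voxel_index
  rows <- list(); cand <- list()
  for (nm in names(templates)) {
    tpl <- templates[[nm]]
    tv <- if (length(dim(tpl)) == 3L) {
      if (!all(dim(tpl) == decomp$grid_shape)) stop("template grid mismatch")
      as.numeric(tpl)[vi]
    } else as.numeric(tpl)
    if (length(tv) != ncol(decomp$spatial_maps)) stop("template voxel-set mismatch")
    rs <- as.numeric(stats::cor(tv, t(decomp$spatial_maps)))
    best <- which.max(rs)   # which.max takes the first (lowest index) on ties
    rows[[nm]] <- data.frame(template = nm, component = best, r = rs[best],
                             matched = rs[best] >= r_min,
                             stringsAsFactors = FALSE)
    cand[[nm]] <- which(rs >= r_min)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "candidates") <- cand
  out
}

#' Write ICA spatial maps as a 4D NIfTI (component axis 4th)
#'
#' @param decomp an `ica_decomposition`.
#' @param path output path.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_ica_maps <- function(decomp, path, voxel_size_mm = c(4, 4, 4)) {
  arr <- array(0, c(decomp$grid_shape, decomp$k))
  for (i in seq_len(decomp$k)) arr[, , , i] <- map_to_3d(decomp, i)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_size_mm, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}
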