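#' Drop initial volumes of a run
#'
#' Removes the first `n_drop` time points (T1 saturation volumes), keeping
#' all metadata.
#'
#' @param run a [bold_run()].
#' @param n_drop number of leading volumes to remove (`0 <= n_drop < t`).
#' @return The shortened `bold_run`.
#' @export
drop_initial_volumes <- function(run, n_drop = 3) {
  stopifnot(inherits(run, "bold_run"))
  t <- n_volumes(run)
  if (n_drop < 0 || n_drop >= t) stop("'n_drop' must be in [0, t)")
  if (n_drop == 0) return(run)
  run$data <- run$data[, , , -seq_len(n_drop), drop = FALSE]
  run
}

# Hat matrix of the local Gaussian-weighted running-line (local linear)
# smoother over n equally spaced time points with kernel SD `sigma` samples.
# Cached per (n, sigma) since it depends only on the record geometry.
.hp_cache <- new.env(parent = emptyenv())
running_line_hat <- function(n, sigma) {
  key <- paste(n, signif(sigma, 12), sep = "_")
  if (!is.null(.hp_cache[[key]])) return(.hp_cache[[key]])
  t_idx <- seq_len(n)
  A <- matrix(0, n, n)
  for (t in t_idx) {
    d <- t_idx - t
    w <- exp(-d^2 / (2 * sigma^2))
    S0 <- sum(w); S1 <- sum(w * d); S2 <- sum(w * d^2)
    denom <- S0 * S2 - S1^2
    A[t, ] <- w * (S2 - d * S1) / denom
  }
  .hp_cache[[key]] <- A
  A
}

#' Temporal high-pass filter (Gaussian running-line detrend)
#'
#' Removes fluctuations slower than the cutoff by subtracting, per voxel, a
#' local Gaussian-weighted running-line fit with kernel SD
#' `cutoff_seconds / (2 * tr_seconds)` volumes, then re-adding the voxel's
#' temporal mean. This is the fslmaths-style nonlinear high-pass; it is
#' characterized by its measured gain curve, not by bit-compatibility with
#' any external tool.
#'
#' @param run a [bold_run()].
#' @param cutoff_seconds high-pass cutoff in seconds (> 2 * TR).
#' @return The filtered `bold_run`.
#' @export
highpass_filter <- function(run, cutoff_seconds = 100) {
  stopifnot(inherits(run, "bold_run"))
  if (cutoff_seconds <= 2 * run$tr_seconds) {
    stop("'cutoff_seconds' must exceed 2 * TR")
  }
  sigma <- cutoff_seconds / (2 * run$tr_seconds)
  n <- n_volumes(run)
  A <- running_line_hat(n, sigma)
  X <- run_matrix(run)            # voxels x time
  trend <- X %*% t(A)
  out <- X - trend + rowMeans(X)
  run$data <- array(out, dim(run$data))
  run
}

# 1D zero-padded convolution matrix for a symmetric kernel on n points.
conv_band_matrix <- function(n, kernel) {
  half <- (length(kernel) - 1L) / 2L
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- (i - half):(i + half)
    ok <- js >= 1L & js <= n
    C[i, js[ok]] <- kernel[ok]
  }
  C
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-half):half)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve each volume of a 4D array along one spatial axis with a 1D kernel
# (zero padding at the grid boundary).
convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_len(4L), axis))
  a <- aperm(arr, perm)
  m <- matrix(a, d[axis], prod(d[-axis]))
  C <- conv_band_matrix(d[axis], kernel)
  m <- C %*% m
  a <- array(m, dim(a))
  aperm(a, order(perm))
}

#' Isotropic Gaussian spatial smoothing
#'
#' Each volume is convolved with a separable Gaussian of SD
#' `fwhm_mm / (2 * sqrt(2 * log(2)))` converted to voxels per axis, with
#' zero padding at the grid boundary. The discrete kernel is normalized to
#' unit mass per axis, so an interior unit impulse integrates to 1.
#'
#' @param run a [bold_run()].
#' @param fwhm_mm kernel full width at half maximum in mm (`0` = identity).
#' @param voxel_size_mm voxel edge lengths in mm (default from the run).
#' @return The smoothed `bold_run`.
#' @export
smooth_gaussian <- function(run, fwhm_mm = 5, voxel_size_mm = run$voxel_size_mm) {
  stopifnot(inherits(run, "bold_run"))
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (fwhm_mm == 0) return(run)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  arr <- run$data
  for (axis in 1:3) {
    arr <- convolve_axis(arr, gaussian_kernel_1d(sigma_mm / voxel_size_mm[axis]),
                         axis)
  }
  run$data <- arr
  run
}

#' Gray-matter mask
#'
#' Wraps a 3D partial-volume map in \[0, 1\] with its thresholded binary
#' form.
#'
#' @param partial_volume 3D array in \[0, 1\].
#' @param threshold binary threshold on the partial volume (default 0.5;
#'   a voxel is in the binary mask when its value strictly exceeds it).
#' @param subject_id source subject.
#' @return A `gm_mask`.
#' @export
gm_mask <- function(partial_volume, threshold = 0.5, subject_id = "subj") {
  if (length(dim(partial_volume)) != 3L) stop("'partial_volume' must be 3D")
  if (any(partial_volume < 0 | partial_volume > 1)) {
    stop("partial volumes must lie in [0, 1]")
  }
  structure(list(partial_volume = partial_volume,
                 binary = partial_volume > threshold,
                 threshold = threshold, subject_id = subject_id),
            class = "gm_mask")
}

#' Resample a gray-matter mask onto a coarser BOLD grid
#'
#' Block-averages the partial-volume map when the mask grid is an integer
#' multiple of the BOLD grid along every axis (the phantom's pre-aligned
#' setting); identical grids pass through unchanged.
#'
#' @param mask a [gm_mask()].
#' @param bold_grid integer length-3 target voxel counts.
#' @return A `gm_mask` on the BOLD grid (same binary threshold).
#' @export
resample_mask_to_bold <- function(mask, bold_grid) {
  stopifnot(inherits(mask, "gm_mask"))
  src <- dim(mask$partial_volume)
  bold_grid <- as.integer(bold_grid)
  if (all(src == bold_grid)) return(mask)
  f <- src / bold_grid
  if (any(f < 1) || any(f != round(f))) {
    stop("mask grid must equal the BOLD grid or be an integer multiple of it")
  }
  f <- as.integer(f)
  pv <- mask$partial_volume
  out <- array(0, bold_grid)
  for (i in seq_len(bold_grid[1])) for (j in seq_len(bold_grid[2])) {
    for (k in seq_len(bold_grid[3])) {
      out[i, j, k] <- mean(pv[((i - 1) * f[1] + 1):(i * f[1]),
                              ((j - 1) * f[2] + 1):(j * f[2]),
                              ((k - 1) * f[3] + 1):(k * f[3])])
    }
  }
  gm_mask(out, threshold = mask$threshold, subject_id = mask$subject_id)
}

#' Restrict a run to gray-matter voxels
#'
#' Zeroes all voxels outside the binary GM mask and records the retained
#' voxel indices (attribute `voxel_index`) so 2D matrices re-project
#' deterministically to the 3D grid downstream.
#'
#' @param run a [bold_run()].
#' @param mask a [gm_mask()] on the same grid.
#' @return The masked `bold_run` with attribute `voxel_index`.
#' @export
apply_gm_mask <- function(run, mask) {
  stopifnot(inherits(run, "bold_run"), inherits(mask, "gm_mask"))
  if (!all(dim(mask$binary) == grid_shape(run))) stop("grid mismatch")
  if (!any(mask$binary)) stop("empty gray-matter mask")
  keep <- which(mask$binary)
  X <- run_matrix(run)
  X[-keep, ] <- 0
  run$data <- array(X, dim(run$data))
  attr(run, "voxel_index") <- keep
  run
}

#' Standard preprocessing chain for one run
#'
#' drop initial volumes -> high-pass filter -> (CV maps are computed at this
#' stage by the QC module) -> Gaussian smoothing. GM masking is applied
#' separately where an analysis arm requires it.
#'
#' @param run a [bold_run()].
#' @param n_drop initial volumes to drop.
#' @param cutoff_seconds high-pass cutoff.
#' @param fwhm_mm smoothing kernel FWHM.
#' @return list with `filtered` (post-filter, pre-smoothing — the QC stage
#'   input) and `smoothed` (analysis-ready) runs.
#' @export
preprocess_run <- function(run, n_drop = 3, cutoff_seconds = 100, fwhm_mm = 5) {
  filtered <- highpass_filter(drop_initial_volumes(run, n_drop), cutoff_seconds)
  list(filtered = filtered, smoothed = smooth_gaussian(filtered, fwhm_mm))
}
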