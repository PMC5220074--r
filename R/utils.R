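# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed for a named stage from a study seed.
# Keeps results independently reproducible per stage while staying < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise sample SD of a voxels x time matrix (divisor t - 1).
row_sd <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

# Band-limited Gaussian noise: white noise filtered to [f_lo, f_hi] Hz in the
# frequency domain, standardized to zero mean and unit sample SD.
bandlimited_noise <- function(n, tr_seconds, band) {
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freqs <- seq(0, n - 1) / (n * tr_seconds)
  # fold to physical frequency (two-sided spectrum)
  freqs <- pmin(freqs, 1 / tr_seconds - freqs)
  keep <- freqs >= band[1] & freqs <= band[2]
  keep[1] <- FALSE
  f[!keep] <- 0
  y <- Re(stats::fft(f, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s < .Machine$double.eps) stop("degenerate band: no frequency bins in [",
                                    band[1], ", ", band[2], "] Hz")
  (y - mean(y)) / s
}

skewness <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) return(0)
  mean(x^3) / s^3
}

# plain numeric array from an RNifti image (drops image attributes/pointers)
nifti_to_array <- function(img) {
  array(as.vector(img), dim(img))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a finite numeric scalar", call. = FALSE)
  }
}
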