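#' ALFF of a single voxel time series
#'
#' The series is discrete-Fourier transformed; the one-sided power spectrum
#' is `|X_k|^2 / N`, doubled for every bin except DC and (for even N) the
#' Nyquist bin, so that the spectrum satisfies Parseval's identity
#' `sum(power) == sum(ts^2)`. ALFF is the mean of the square root of the
#' power over the bins whose frequency f satisfies `low <= f <= high`
#' (band edges inclusive). No windowing is applied before the transform.
#'
#' Absolute (unstandardized) ALFF values depend on this normalization
#' convention; the global-mean standardization of
#' [standardize_global_mean()] divides any fixed convention out.
#'
#' @param ts Numeric time series (length >= 8).
#' @param tr_s Sampling interval in seconds.
#' @param band_hz Length-2 pass band in Hz, within the Nyquist range.
#' @return Nonnegative scalar ALFF value.
#' @export
compute_alff_voxel <- function(ts, tr_s, band_hz = c(0.01, 0.08)) {
  n <- length(ts)
  if (n < 8) stop("ALFF needs a series of at least 8 points")
  sel <- alff_band_bins(n, tr_s, band_hz)
  p <- one_sided_power(stats::fft(ts), n)
  mean(sqrt(p[sel$bins]))
}

# One-sided power spectrum with Parseval-preserving doubling.
# X: full DFT; returns power for bins k = 0..floor(n/2) (1-based index k+1).
one_sided_power <- function(X, n) {
  m <- floor(n / 2)
  p <- Mod(X[1:(m + 1)])^2 / n
  dbl <- rep(2, m + 1)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[m + 1] <- 1
  p * dbl
}

# Indices (into the one-sided spectrum) of bins with low <= f <= high.
alff_band_bins <- function(n, tr_s, band_hz) {
  nyq <- 1 / (2 * tr_s)
  if (!(0 < band_hz[1] && band_hz[1] < band_hz[2] && band_hz[2] <= nyq))
    stop("band must lie within (0, Nyquist]")
  f <- (0:floor(n / 2)) / (n * tr_s)
  bins <- which(f >= band_hz[1] & f <= band_hz[2])
  if (!length(bins)) {
    need <- ceiling(1 / (tr_s * (band_hz[2] - band_hz[1])))
    stop("no DFT bins inside the band; need a series of at least ~",
         need, " points")
  }
  list(bins = bins, f = f[bins])
}

#' Voxelwise ALFF map
#'
#' Applies [compute_alff_voxel()] to every in-mask voxel of a preprocessed
#' volume (vectorized over voxels).
#'
#' @param vol Preprocessed [volume4d()].
#' @param mask Logical 3D brain mask.
#' @param band_hz Pass band in Hz.
#' @return An `alff_map`: list with 3D `values` (0 outside the mask),
#'   `band_hz`, `standardized = FALSE` and the `mask`.
#' @export
compute_alff_map <- function(vol, mask, band_hz = c(0.01, 0.08)) {
  check_mask(mask, grid_dims(vol))
  if (!any(mask)) stop("empty brain mask")
  Y <- mask_matrix(vol, mask)
  n <- nrow(Y)
  sel <- alff_band_bins(n, vol$tr, band_hz)
  G <- stats::mvfft(Y)
  m <- floor(n / 2)
  dbl <- rep(2, m + 1); dbl[1] <- 1
  if (n %% 2 == 0) dbl[m + 1] <- 1
  P <- Mod(G[1:(m + 1), , drop = FALSE])^2 / n * dbl
  vals <- colMeans(sqrt(P[sel$bins, , drop = FALSE]))
  structure(list(values = embed_map(vals, mask), band_hz = band_hz,
                 standardized = FALSE, mask = mask),
            class = "alff_map")
}

#' Global-mean standardization of an ALFF map
#'
#' Divides every in-mask value by the mean over the brain mask (not the full
#' grid), so the standardized map has in-mask mean 1.
#'
#' @param map An `alff_map`.
#' @param mask Optional mask overriding the one stored in `map`.
#' @return Standardized `alff_map`.
#' @export
standardize_global_mean <- function(map, mask = map$mask) {
  g <- mean(map$values[as.logical(mask)])
  if (!is.finite(g) || g <= 0) stop("global mean ALFF must be positive")
  map$values <- map$values / g
  map$values[!mask] <- 0
  map$standardized <- TRUE
  map$mask <- mask
  map
}

#' @export
print.alff_map <- function(x, ...) {
  v <- x$values[as.logical(x$mask)]
  cat(sprintf("<alff_map> %s, band %.3g-%.3g Hz, %d in-mask voxels, mean %.4g\n",
              if (x$standardized) "standardized" else "raw",
              x$band_hz[1], x$band_hz[2], length(v), mean(v)))
  invisible(x)
}
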