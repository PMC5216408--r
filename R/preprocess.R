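#' Rigid-body motion trace
#'
#' @param params t x 6 numeric matrix: columns 1-3 translations in mm,
#'   columns 4-6 rotations in radians, one row per volume.
#' @param tr Repetition time in seconds.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(params, tr = 2) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion parameters must have 6 columns")
  structure(list(params = params, tr = tr), class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames, mean FD %.3f mm\n",
              nrow(x$params), framewise_displacement(x)$mean_fd))
  invisible(x)
}

#' Discard initial volumes
#'
#' Removes the first `n` timepoints from a volume and its motion trace
#' synchronously (magnetization-equilibration discard).
#'
#' @param vol A [volume4d()].
#' @param motion A [motion_trace()] with one row per volume.
#' @param n Number of initial volumes to drop (default 10).
#' @return List with elements `vol` and `motion`.
#' @export
discard_initial_volumes <- function(vol, motion, n = 10) {
  nt <- n_volumes(vol)
  if (nrow(motion$params) != nt)
    stop("motion trace rows must equal volume count before discarding")
  if (nt <= n) stop("cannot discard ", n, " of ", nt, " volumes")
  if (n == 0) return(list(vol = vol, motion = motion))
  keep <- (n + 1):nt
  v <- volume4d(vol$data[, , , keep, drop = FALSE], vol$voxel_size, vol$tr, vol$affine)
  list(vol = v, motion = motion_trace(motion$params[keep, , drop = FALSE], motion$tr))
}

#' Gross-motion exclusion rule
#'
#' A run is excluded when the maximum absolute translation exceeds
#' `trans_mm` in any axis or the maximum absolute rotation exceeds
#' `rot_deg` (degrees; the trace stores radians) in any axis.
#'
#' @param motion A [motion_trace()].
#' @param trans_mm Translation limit in mm (default 3).
#' @param rot_deg Rotation limit in degrees (default 3).
#' @return `TRUE` if the run should be excluded.
#' @export
motion_exclusion <- function(motion, trans_mm = 3, rot_deg = 3) {
  p <- motion$params
  max(abs(p[, 1:3])) > trans_mm || max(abs(p[, 4:6])) > rot_deg * pi / 180
}

#' Framewise displacement
#'
#' FD at frame t (t >= 2) is the sum of absolute backward differences of the
#' three translations plus `sphere_radius_mm` times the sum of absolute
#' differences of the three rotations (small-angle arc length on a sphere of
#' 50 mm radius). FD of the first frame is 0; `mean_fd` averages over all
#' frames including the leading zero.
#'
#' @param motion A [motion_trace()].
#' @param sphere_radius_mm Radius converting radians to mm (default 50).
#' @return List with `fd` (length-t series) and `mean_fd`.
#' @export
framewise_displacement <- function(motion, sphere_radius_mm = 50) {
  p <- motion$params
  if (nrow(p) < 2) stop("framewise displacement needs at least 2 frames")
  d <- abs(diff(p))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd))
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3.5 * sigma_vox))
  k <- exp(-(-r:r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Dense convolution matrix for one axis with zero-padding at the borders.
conv_matrix_1d <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  S <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    S[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  S
}

# Apply a separable per-axis linear operator to a 4D array.
apply_separable <- function(a, Sx, Sy, Sz) {
  d <- dim(a)
  a <- array(Sx %*% matrix(a, d[1]), d)
  a <- aperm(a, c(2, 1, 3, 4))
  a <- array(Sy %*% matrix(a, d[2]), dim(a))
  a <- aperm(a, c(2, 1, 3, 4))
  a <- aperm(a, c(3, 1, 2, 4))
  a <- array(Sz %*% matrix(a, d[3]), dim(a))
  aperm(a, c(2, 3, 1, 4))
}

#' Spatial Gaussian smoothing
#'
#' Convolves each 3D frame with a separable isotropic Gaussian kernel of the
#' requested full width at half maximum, sigma = fwhm / (2 sqrt(2 ln 2)) per
#' axis in mm converted to voxels. Values outside the grid are treated as
#' zero (zero-padding, no masked renormalization). The convolution runs in
#' compiled code; a plain-R reference path (`reference = TRUE`) implements
#' the identical operator with per-axis convolution matrices.
#'
#' @param vol A [volume4d()].
#' @param fwhm_mm Kernel FWHM in mm (default 8); 0 returns the input.
#' @param reference Use the plain-R reference implementation (default FALSE).
#' @return Smoothed `volume4d`.
#' @export
smooth_gaussian <- function(vol, fwhm_mm = 8, reference = FALSE) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel_size
  d <- dim(vol$data)
  kx <- gaussian_kernel_1d(sig[1])
  ky <- gaussian_kernel_1d(sig[2])
  kz <- gaussian_kernel_1d(sig[3])
  out <- if (reference) {
    apply_separable(vol$data, conv_matrix_1d(d[1], kx),
                    conv_matrix_1d(d[2], ky), conv_matrix_1d(d[3], kz))
  } else {
    .conv_separable_4d(vol$data, as.integer(d), kx, ky, kz)
  }
  volume4d(out, vol$voxel_size, vol$tr, vol$affine)
}

#' Linear detrending
#'
#' Removes the least-squares fit of an intercept plus linear ramp from each
#' column of a time-series matrix (or from a single series).
#'
#' @param ts Numeric vector or t x V matrix.
#' @return Residual series of the same shape, mean approximately zero.
#' @export
detrend_linear <- function(ts) {
  v <- is.null(dim(ts))
  Y <- if (v) matrix(ts, ncol = 1) else ts
  nt <- nrow(Y)
  if (nt < 3) stop("detrending needs at least 3 timepoints")
  X <- cbind(1, seq_len(nt))
  R <- qr.resid(qr(X), Y)
  if (v) drop(R) else R
}

#' Friston-24 motion regressor expansion
#'
#' Expands the 6 rigid-body parameters R(t) into 24 columns:
#' R(t), R(t)^2, R(t-1), R(t-1)^2, with the lagged rows at t = 1 zero-filled.
#'
#' @param motion A [motion_trace()].
#' @return t x 24 matrix with labelled columns.
#' @export
friston24_expand <- function(motion) {
  R <- motion$params
  if (nrow(R) < 2) stop("Friston-24 expansion needs at least 2 frames")
  Rlag <- rbind(0, R[-nrow(R), , drop = FALSE])
  out <- cbind(R, R^2, Rlag, Rlag^2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(base, paste0(base, "_sq"), paste0(base, "_lag"),
                     paste0(base, "_lag_sq"))
  out
}

#' Mean tissue time series
#'
#' Per-frame spatial mean of a volume over white-matter and CSF masks.
#'
#' @param vol A [volume4d()].
#' @param wm_mask,csf_mask Logical 3D arrays.
#' @return List with `wm` and `csf` time series.
#' @export
extract_tissue_means <- function(vol, wm_mask, csf_mask) {
  one <- function(mask, label) {
    check_mask(mask, grid_dims(vol))
    if (!any(mask)) stop("empty ", label, " mask")
    rowMeans(mask_matrix(vol, mask))
  }
  list(wm = one(wm_mask, "white-matter"), csf = one(csf_mask, "CSF"))
}

#' Build the default nuisance regressor set
#'
#' Friston-24 motion expansion plus white-matter and CSF mean signals
#' (26 columns, no constant column).
#'
#' @param motion A [motion_trace()] (post-discard).
#' @param vol A [volume4d()] (post-discard) from which tissue means are taken.
#' @param wm_mask,csf_mask Logical 3D masks.
#' @return t x 26 matrix.
#' @export
build_nuisance <- function(motion, vol, wm_mask, csf_mask) {
  tissue <- extract_tissue_means(vol, wm_mask, csf_mask)
  cbind(friston24_expand(motion), wm = tissue$wm, csf = tissue$csf)
}

#' Nuisance regression
#'
#' Regresses an intercept plus the nuisance columns out of every in-mask
#' voxel series; residuals are orthogonal to every retained regressor.
#' Linearly dependent nuisance columns are dropped with a warning.
#'
#' @param vol A [volume4d()].
#' @param nuisance t x k matrix of nuisance regressors (no constant column).
#' @param mask Logical 3D brain mask.
#' @return `volume4d` of residuals (zero outside the mask).
#' @export
regress_nuisance <- function(vol, nuisance, mask) {
  nt <- n_volumes(vol)
  if (nrow(nuisance) != nt) stop("nuisance rows must match volume count")
  X <- cbind(intercept = 1, nuisance)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[-seq_len(qx$rank)]
    warning("dropping ", length(drop_idx),
            " linearly dependent nuisance column(s): ",
            paste(colnames(X)[drop_idx], collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  if (nt <= ncol(X)) stop("need more timepoints than regressors")
  Y <- mask_matrix(vol, mask)
  unmask_matrix(vol, qr.resid(qx, Y), mask)
}

#' Ideal band-pass filter
#'
#' Frequency-domain brick-wall filter: each in-mask voxel series is Fourier
#' transformed, every bin whose frequency lies outside `[low_hz, high_hz]`
#' (including DC and the mirrored negative frequencies) is zeroed, and the
#' series inverse transformed. The output is exactly real.
#'
#' @param vol A [volume4d()].
#' @param low_hz,high_hz Pass band in Hz (defaults 0.01 and 0.08).
#' @param mask Logical 3D brain mask.
#' @return Filtered `volume4d` (zero outside the mask).
#' @export
bandpass_filter <- function(vol, low_hz = 0.01, high_hz = 0.08, mask) {
  nt <- n_volumes(vol)
  nyq <- 1 / (2 * vol$tr)
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq))
    stop(sprintf("band must satisfy 0 < low < high < Nyquist = %.4g Hz", nyq))
  Y <- mask_matrix(vol, mask)
  f <- dft_frequencies(nt, vol$tr)
  keep <- f >= low_hz & f <= high_hz
  G <- stats::mvfft(Y)
  G[!keep, ] <- 0
  unmask_matrix(vol, Re(stats::mvfft(G, inverse = TRUE)) / nt, mask)
}

# Two-sided DFT bin frequencies folded to [0, Nyquist].
dft_frequencies <- function(n, tr) {
  k <- 0:(n - 1)
  pmin(k, n - k) / (n * tr)
}

#' Temporal preprocessing pipeline for one subject
#'
#' Fixed, logged order: discard initial volumes, spatial Gaussian smoothing,
#' linear detrending, nuisance regression (Friston-24 + WM + CSF), ideal
#' band-pass filtering. Tissue signals are extracted from the smoothed,
#' detrended data. Registration steps (slice timing, realignment,
#' normalization) are outside the scope of this package: inputs are assumed
#' to share a grid, with motion supplied as parameter files.
#'
#' @param vol Raw [volume4d()].
#' @param motion [motion_trace()] with one row per raw volume.
#' @param brain_mask,wm_mask,csf_mask Logical 3D masks.
#' @param discard Initial volumes to drop (default 10).
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 8).
#' @param band Pass band in Hz (default `c(0.01, 0.08)`).
#' @param trans_mm,rot_deg Gross-motion exclusion limits (defaults 3 mm / 3 deg).
#' @return List: `vol` (preprocessed residual volume), `motion` (post-discard),
#'   `mean_fd`, `exclude` (gross-motion flag), `steps` (log of applied steps).
#' @export
preprocess_subject <- function(vol, motion, brain_mask, wm_mask, csf_mask,
                               discard = 10, fwhm_mm = 8,
                               band = c(0.01, 0.08),
                               trans_mm = 3, rot_deg = 3) {
  exclude <- motion_exclusion(motion, trans_mm, rot_deg)
  d <- discard_initial_volumes(vol, motion, discard)
  fd <- framewise_displacement(d$motion)
  v <- smooth_gaussian(d$vol, fwhm_mm)
  # all temporal steps operate on one in-mask matrix (same operation
  # sequence as the standalone functions, without full-grid round trips)
  Y <- detrend_linear(mask_matrix(v, brain_mask))
  inb <- which(as.logical(brain_mask))
  wm_cols <- match(which(as.logical(wm_mask)), inb)
  csf_cols <- match(which(as.logical(csf_mask)), inb)
  if (anyNA(wm_cols) || anyNA(csf_cols))
    stop("tissue masks must lie inside the brain mask")
  nuis <- cbind(friston24_expand(d$motion),
                wm = rowMeans(Y[, wm_cols, drop = FALSE]),
                csf = rowMeans(Y[, csf_cols, drop = FALSE]))
  X <- cbind(1, nuis)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("dropping ", ncol(X) - qx$rank,
            " linearly dependent nuisance column(s)")
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  Y <- qr.resid(qx, Y)
  nt <- nrow(Y)
  nyq <- 1 / (2 * v$tr)
  if (!(0 < band[1] && band[1] < band[2] && band[2] < nyq))
    stop("band must satisfy 0 < low < high < Nyquist")
  keep <- dft_frequencies(nt, v$tr) >= band[1] &
    dft_frequencies(nt, v$tr) <= band[2]
  G <- stats::mvfft(Y)
  G[!keep, ] <- 0
  Y <- Re(stats::mvfft(G, inverse = TRUE)) / nt
  v <- unmask_matrix(v, Y, brain_mask)
  list(vol = v, motion = d$motion, mean_fd = fd$mean_fd, exclude = exclude,
       steps = c("discard", "smooth", "detrend", "nuisance", "bandpass"))
}
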