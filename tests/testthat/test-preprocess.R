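make_vol <- function(gd = c(6, 6, 6), nt = 40, tr = 2, fill = NULL) {
  dat <- if (is.null(fill)) array(rnorm(prod(gd) * nt), c(gd, nt))
  else array(fill, c(gd, nt))
  volume4d(dat, tr = tr)
}

test_that("initial-volume discarding drops timepoints synchronously", {
  vol <- make_vol(nt = 180)
  mo <- motion_trace(matrix(rnorm(180 * 6, 0, 0.01), 180, 6))
  d <- discard_initial_volumes(vol, mo, 10)
  expect_equal(dim(d$vol$data)[4], 170)
  expect_equal(nrow(d$motion$params), 170)
  expect_equal(d$vol$data[, , , 1], vol$data[, , , 11])
  id <- discard_initial_volumes(vol, mo, 0)
  expect_identical(id$vol$data, vol$data)
  small <- make_vol(nt = 8)
  expect_error(discard_initial_volumes(small, motion_trace(matrix(0, 8, 6)), 10),
               "cannot discard")
})

test_that("gross-motion exclusion triggers on 3 mm / 3 degree breaches", {
  zero <- motion_trace(matrix(0, 20, 6))
  expect_false(motion_exclusion(zero))
  p <- matrix(0, 20, 6); p[7, 1] <- 3.5
  expect_true(motion_exclusion(motion_trace(p)))
  p2 <- matrix(0, 20, 6); p2[4, 5] <- 3.5 * pi / 180  # 3.5 degrees in radians
  expect_true(motion_exclusion(motion_trace(p2)))
  p3 <- matrix(0, 20, 6); p3[4, 5] <- 2.5 * pi / 180
  expect_false(motion_exclusion(motion_trace(p3)))
})

test_that("framewise displacement follows the 50 mm sum-of-differences form", {
  expect_equal(framewise_displacement(motion_trace(matrix(0, 10, 6)))$mean_fd, 0)
  p <- matrix(0, 5, 6); p[3, 1] <- 1   # out and back: two unit displacements
  fd <- framewise_displacement(motion_trace(p))$fd
  expect_equal(fd, c(0, 0, 1, 1, 0))
  pr <- matrix(0, 3, 6); pr[2, 4] <- 0.01
  expect_equal(framewise_displacement(motion_trace(pr))$fd[2], 0.5)  # 50 mm * 0.01 rad
})

test_that("Gaussian smoothing has the requested FWHM and matches the R reference", {
  gd <- c(21, 21, 21)
  dat <- array(0, c(gd, 1)); dat[11, 11, 11, 1] <- 1
  vol <- volume4d(dat, voxel_size = c(3, 3, 3), tr = 2)
  sm <- smooth_gaussian(vol, 8)
  prof <- sm$data[, 11, 11, 1]
  half <- max(prof) / 2
  # linear interpolation of the half-maximum crossings, in mm
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  cross <- function(i1, i2)
    i1 + (i2 - i1) * (half - prof[i1]) / (prof[i2] - prof[i1])
  fwhm_mm <- (cross(hi, hi + 1) - cross(lo, lo - 1)) * 3
  expect_equal(fwhm_mm, 8, tolerance = 0.08)
  expect_identical(smooth_gaussian(vol, 0)$data, vol$data)
  const <- make_vol(gd = c(12, 12, 12), nt = 2, fill = 5)
  smc <- smooth_gaussian(const, 8)
  expect_equal(smc$data[6, 6, 6, 1], 5, tolerance = 1e-6)  # away from borders
  rvol <- make_vol(gd = c(9, 8, 7), nt = 3)
  expect_equal(smooth_gaussian(rvol, 8)$data,
               smooth_gaussian(rvol, 8, reference = TRUE)$data,
               tolerance = 1e-12)
})

test_that("linear detrending removes ramps and is an orthogonal projection", {
  t <- 1:50
  line <- 2.5 + 0.3 * t
  expect_equal(detrend_linear(line), rep(0, 50), tolerance = 1e-10)
  set.seed(3)
  y <- rnorm(50)
  r <- detrend_linear(y)
  expect_equal(sum(r), 0, tolerance = 1e-10)
  expect_equal(sum(r * t), 0, tolerance = 1e-8)
  # a sinusoid changes only by its projection onto [1, t]
  s <- sin(2 * pi * (0:49) / 10)
  X <- cbind(1, t)
  proj <- X %*% solve(crossprod(X), crossprod(X, s))
  expect_equal(detrend_linear(s), s - drop(proj), tolerance = 1e-10)
})

test_that("Friston-24 expansion has the documented column structure", {
  zero <- friston24_expand(motion_trace(matrix(0, 12, 6)))
  expect_equal(dim(zero), c(12L, 24L))
  expect_true(all(zero == 0))
  set.seed(4)
  R <- matrix(rnorm(60), 10, 6)
  f24 <- friston24_expand(motion_trace(R))
  expect_equal(ncol(f24), 24)
  expect_equal(f24[, 7:12], R^2, ignore_attr = TRUE)
  expect_equal(f24[1, 13:24], rep(0, 12), ignore_attr = TRUE)
  expect_equal(f24[2:10, 13:18], R[1:9, ], ignore_attr = TRUE)
  expect_equal(f24[, 19:24], f24[, 13:18]^2, ignore_attr = TRUE)
})

test_that("tissue means extract per-frame spatial averages", {
  gd <- c(4, 4, 4); nt <- 6
  dat <- array(2, c(gd, nt)); dat[1, 1, 1, ] <- 8
  vol <- volume4d(dat, tr = 2)
  wm <- array(FALSE, gd); wm[1, 1, 1] <- TRUE           # single voxel
  csf <- array(FALSE, gd); csf[3:4, , ] <- TRUE
  tm <- extract_tissue_means(vol, wm, csf)
  expect_equal(tm$wm, rep(8, nt))
  expect_equal(tm$csf, rep(2, nt))
  expect_error(extract_tissue_means(vol, array(FALSE, gd), csf), "empty")
})

test_that("nuisance regression leaves residuals orthogonal to all regressors", {
  set.seed(6)
  gd <- c(4, 4, 2); nt <- 60
  mask <- array(TRUE, gd)
  nuis <- matrix(rnorm(nt * 5), nt, 5)
  vol <- make_vol(gd, nt)
  # plant one voxel equal to a nuisance column
  vol$data[1, 1, 1, ] <- nuis[, 3]
  out <- regress_nuisance(vol, nuis, mask)
  expect_equal(max(abs(out$data[1, 1, 1, ])), 0, tolerance = 1e-10)
  Y <- mask_matrix(out, mask)
  X <- cbind(1, nuis)
  expect_lt(max(abs(crossprod(X, Y))) / nt, 1e-10)
  # rank-deficient design: duplicated column is dropped with a warning
  expect_warning(regress_nuisance(vol, cbind(nuis, nuis[, 1]), mask),
                 "dependent")
})

test_that("ideal band-pass keeps in-band and annihilates out-of-band energy", {
  gd <- c(2, 2, 1); nt <- 200; tr <- 2
  mask <- array(TRUE, gd)
  t <- (0:(nt - 1)) * tr
  inband <- sin(2 * pi * 0.04 * t)
  outband <- sin(2 * pi * 0.2 * t)
  dat <- array(0, c(gd, nt))
  dat[1, 1, 1, ] <- inband
  dat[2, 1, 1, ] <- outband
  dat[1, 2, 1, ] <- inband + outband
  dat[2, 2, 1, ] <- rnorm(nt)
  vol <- volume4d(dat, tr = tr)
  out <- bandpass_filter(vol, 0.01, 0.08, mask)
  expect_equal(out$data[1, 1, 1, ], inband, tolerance = 1e-6)
  expect_lt(max(abs(out$data[2, 1, 1, ])), 1e-10)
  expect_equal(out$data[1, 2, 1, ], inband, tolerance = 1e-6)
  # Parseval check: residual out-of-band power is numerically zero
  y <- out$data[2, 2, 1, ]
  p <- alffdev:::one_sided_power(fft(y), nt)
  f <- (0:(nt / 2)) / (nt * tr)
  oob <- sum(p[f < 0.01 | f > 0.08])
  expect_lt(oob / sum(p), 1e-10)
  expect_error(bandpass_filter(vol, 0.01, 0.3, mask), "Nyquist")
})

test_that("temporal preprocessing is linear in its input", {
  set.seed(8)
  cfg <- tiny_config()
  mo <- generate_motion_trace(cfg, 3)
  v1 <- make_vol(cfg$grid_dims, cfg$n_volumes)
  v2 <- make_vol(cfg$grid_dims, cfg$n_volumes)
  vsum <- volume4d(v1$data + v2$data, tr = 2)
  args <- list(motion = mo, brain_mask = cfg$brain_mask,
               wm_mask = cfg$wm_mask, csf_mask = cfg$csf_mask)
  p1 <- do.call(preprocess_subject, c(list(v1), args))
  p2 <- do.call(preprocess_subject, c(list(v2), args))
  ps <- do.call(preprocess_subject, c(list(vsum), args))
  # nuisance regressors differ across inputs (tissue means are data-derived),
  # so linearity holds for the deterministic chain with a fixed nuisance set;
  # check it on the smoothing + detrend + band-pass composition instead
  chain <- function(v) {
    d <- discard_initial_volumes(v, mo, 10)
    s <- smooth_gaussian(d$vol, 8)
    b <- bandpass_filter(unmask_matrix(s, detrend_linear(
      mask_matrix(s, cfg$brain_mask)), cfg$brain_mask),
      0.01, 0.08, cfg$brain_mask)
    b$data
  }
  expect_equal(chain(vsum), chain(v1) + chain(v2), tolerance = 1e-8)
})

test_that("the one-pass pipeline equals the composed standalone operations", {
  set.seed(10)
  cfg <- tiny_config()
  ph <- generate_phenotypes(tiny_cohort(1), 1)
  vol <- generate_subject_volume(ph[1, ], cfg, 2)
  mo <- generate_motion_trace(cfg, 3)
  pp <- preprocess_subject(vol, mo, cfg$brain_mask, cfg$wm_mask, cfg$csf_mask)
  d <- discard_initial_volumes(vol, mo, 10)
  v <- smooth_gaussian(d$vol, 8)
  v <- unmask_matrix(v, detrend_linear(mask_matrix(v, cfg$brain_mask)),
                     cfg$brain_mask)
  nuis <- build_nuisance(d$motion, v, cfg$wm_mask, cfg$csf_mask)
  v <- regress_nuisance(v, nuis, cfg$brain_mask)
  v <- bandpass_filter(v, 0.01, 0.08, cfg$brain_mask)
  expect_equal(pp$vol$data, v$data, tolerance = 1e-10)
  expect_equal(pp$steps,
               c("discard", "smooth", "detrend", "nuisance", "bandpass"))
})
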