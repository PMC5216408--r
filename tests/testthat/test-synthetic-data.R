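test_that("default cohort reproduces the 128-subject 2x3 design", {
  ph <- generate_phenotypes(seed = 1)
  expect_equal(nrow(ph), 128)
  expect_equal(as.vector(table(ph$diagnosis)), c(64, 64))
  counts <- table(ph$diagnosis, ph$cohort)
  expect_equal(as.vector(counts["ASD", ]), c(18, 28, 18))
  expect_equal(as.vector(counts["TC", ]), c(20, 26, 18))
  # ages within cohort bounds and within 3 SD of the cohort mean
  for (ch in levels(ph$cohort)) {
    a <- ph$age_years[ph$cohort == ch]
    expect_true(all(abs(a - mean(a)) <= 3 * sd(a)))
  }
  expect_true(all(is.na(ph$ados_social[ph$diagnosis == "TC"])))
})

test_that("minimal and degenerate cohort specs are handled", {
  ph1 <- generate_phenotypes(tiny_cohort(1), seed = 2)
  expect_equal(nrow(ph1), 6)
  expect_equal(as.vector(table(ph1$diagnosis, ph1$cohort)), rep(1L, 6))
  expect_error(cohort_spec(cell_sizes = list(child = c(ASD = 0, TC = 1),
                                             adolescent = c(ASD = 1, TC = 1),
                                             adult = c(ASD = 1, TC = 1))),
               "positive")
  expect_error(cohort_spec(age_ranges = list(child = c(6, 12),
                                             adolescent = c(11, 18),
                                             adult = c(18.6, 32))),
               "disjoint")
})

test_that("generation is deterministic given the seed", {
  expect_identical(generate_phenotypes(seed = 7), generate_phenotypes(seed = 7))
  cfg <- tiny_config()
  m1 <- generate_motion_trace(cfg, 5)
  m2 <- generate_motion_trace(cfg, 5)
  expect_identical(m1$params, m2$params)
  ph <- generate_phenotypes(tiny_cohort(1), 3)
  v1 <- generate_subject_volume(ph[1, ], cfg, 9)
  v2 <- generate_subject_volume(ph[1, ], cfg, 9)
  expect_identical(v1$data, v2$data)
})

test_that("motion traces follow the random-walk model", {
  cfg <- simulation_config()
  mo <- generate_motion_trace(cfg, 1)
  expect_equal(dim(mo$params), c(180L, 6L))
  expect_equal(mo$params[1, ], rep(0, 6), ignore_attr = TRUE)
  frozen <- simulation_config(motion_step_sd = c(trans = 0, rot = 0))
  mz <- generate_motion_trace(frozen, 1)
  expect_true(all(mz$params == 0))
  expect_equal(framewise_displacement(mz)$mean_fd, 0)
  out <- generate_motion_trace(cfg, 1, outlier = TRUE)
  expect_true(motion_exclusion(out))
})

test_that("planted amplitudes scale regional ALFF per the closed form", {
  cfg0 <- tiny_config(background_sd = 0)   # noiseless: exact closed form
  ph <- generate_phenotypes(tiny_cohort(1), 4)
  rec <- ph[ph$diagnosis == "TC", ][1, ]
  amps <- c(mPFC = 0.8, precuneus = 0.5)
  vol <- generate_subject_volume(rec, cfg0, 11, amplitudes = amps)
  d <- discard_initial_volumes(vol, motion_trace(matrix(0, 80, 6)), 10)
  map <- compute_alff_map(d$vol, cfg0$brain_mask)
  reg <- cfg0$regions$mPFC$voxel_set
  n <- 70
  n_band <- sum({k <- 0:(n / 2); fk <- k / (n * 2); fk >= 0.01 & fk <= 0.08})
  # K sinusoids of per-sinusoid amplitude A sqrt(2/K) on distinct bins:
  # ALFF = K * A * sqrt(2/K) * sqrt(n/2) / n_band = A sqrt(K n) / n_band
  expected <- 0.8 * sqrt(5 * n) / n_band
  expect_equal(mean(map$values[reg]), expected, tolerance = 1e-10)
  # doubling the amplitude doubles regional ALFF
  vol2 <- generate_subject_volume(rec, cfg0, 11, amplitudes = 2 * amps)
  map2 <- compute_alff_map(discard_initial_volumes(
    vol2, motion_trace(matrix(0, 80, 6)), 10)$vol, cfg0$brain_mask)
  expect_equal(mean(map2$values[reg]), 2 * expected, tolerance = 1e-10)
})

test_that("zero planted amplitude leaves regions at background ALFF", {
  cfg <- tiny_config()
  ph <- generate_phenotypes(tiny_cohort(1), 4)
  vol <- generate_subject_volume(ph[1, ], cfg, 12,
                                 amplitudes = c(mPFC = 0, precuneus = 0))
  map <- compute_alff_map(vol, cfg$brain_mask)
  reg <- cfg$regions$mPFC$voxel_set
  bg <- cfg$brain_mask & !reg & !cfg$regions$precuneus$voxel_set
  expect_equal(mean(map$values[reg]), mean(map$values[bg]), tolerance = 0.1)
  expect_true(all(map$values[!cfg$brain_mask] == 0))
})

test_that("symptom scores couple to amplitudes as configured", {
  ph <- generate_phenotypes(tiny_cohort(4), 5)
  amps <- matrix(runif(nrow(ph) * 2, 0.5, 1.5), nrow(ph), 2,
                 dimnames = list(ph$subject_id, c("mPFC", "precuneus")))
  zero_w <- list(weights = c(mPFC = 0, precuneus = 0), intercept = 5,
                 noise_sd = 0, range = c(0, 14))
  s0 <- generate_symptoms(ph, amps, zero_w, 6)
  expect_true(all(s0$ados_social[s0$diagnosis == "ASD"] == 5))
  lin <- list(weights = c(mPFC = 2, precuneus = 3), intercept = 1,
              noise_sd = 0, range = c(-100, 100))
  s1 <- generate_symptoms(ph, amps, lin, 6)
  asd <- which(ph$diagnosis == "ASD")
  expect_equal(s1$ados_social[asd],
               round(1 + drop(amps[asd, ] %*% c(2, 3))),
               ignore_attr = TRUE)
  expect_true(all(is.na(s1$ados_social[-asd])))
})

test_that("roster construction and exclusion rules recover 128 of 184", {
  cfg <- simulation_config()
  roster <- generate_roster(seed = 1)
  expect_equal(nrow(roster), 184)
  traces <- lapply(seq_len(nrow(roster)), function(i)
    generate_motion_trace(cfg, alffdev:::subseed(1, 90, i),
                          outlier = roster$motion_outlier[i]))
  kept <- cohort_filter(roster, traces)
  excl <- attr(kept, "n_excluded")
  expect_equal(unname(excl["motion"]), 7)
  expect_equal(unname(excl["matching"]), 49)
  expect_equal(nrow(kept), 128)
  expect_equal(as.vector(table(kept$diagnosis)), c(64, 64))
})

test_that("a cohort of traces with exactly 7 planted breaches yields 7 exclusions", {
  cfg <- simulation_config()
  flags <- rep(c(TRUE, FALSE), c(7, 177))
  traces <- lapply(seq_along(flags), function(i)
    generate_motion_trace(cfg, 1000 + i, outlier = flags[i]))
  excl <- vapply(traces, motion_exclusion, logical(1))
  expect_equal(sum(excl), 7)
  expect_equal(which(excl), 1:7)
})

test_that("written datasets round-trip and the manifest seed replays identically", {
  cfg <- tiny_config(n_volumes = 60)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(cfg, tiny_cohort(1), seed = 21, dir = dir,
                         keep_volumes = TRUE)
  expect_equal(nrow(ds$phenotypes), 6)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  vol_back <- read_volume(file.path(
    dir, sprintf("%s_bold.nii.gz", ds$phenotypes$subject_id[1])))
  expect_equal(vol_back$data, ds$volumes[[1]]$data, tolerance = 1e-7)
  expect_equal(vol_back$tr, 2)
  mo_back <- read_motion(file.path(
    dir, sprintf("%s_motion.txt", ds$phenotypes$subject_id[1])))
  expect_equal(mo_back$params, ds$traces[[1]]$params, tolerance = 1e-8,
               ignore_attr = TRUE)
  mask_back <- read_mask(file.path(dir, "brain_mask.nii.gz"))
  expect_identical(mask_back, cfg$brain_mask)
  # replaying the manifest seed regenerates the identical dataset
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  ds2 <- generate_dataset(cfg, tiny_cohort(1), seed = man$seed,
                          keep_volumes = TRUE)
  expect_identical(ds2$volumes[[1]]$data, ds$volumes[[1]]$data)
  expect_identical(ds2$phenotypes, ds$phenotypes)
})
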