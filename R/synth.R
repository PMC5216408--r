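#' Cohort specification for the synthetic study sample
#'
#' Defaults reproduce the study design: a 2 (diagnosis: ASD, TC) by
#' 3 (age cohort: child < 11 y, adolescent 11 to < 18 y, adult >= 18 y)
#' between-subject layout with cell sizes 18/20, 28/26, 18/18 (128 subjects,
#' 64 per diagnosis), male proportions and full-scale IQ distributions per
#' cell matching the published sample characteristics.
#'
#' @param cell_sizes Named list per cohort of `c(ASD = n, TC = n)` counts.
#' @param age_ranges Named list per cohort of closed age intervals in years.
#' @param p_male Named numeric, probability of gender code 1 (male) per cohort.
#' @param fiq Named list per cohort of list(ASD = c(mean, sd), TC = c(mean, sd)).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    cell_sizes = list(child = c(ASD = 18, TC = 20),
                      adolescent = c(ASD = 28, TC = 26),
                      adult = c(ASD = 18, TC = 18)),
    age_ranges = list(child = c(6.5, 10.9),
                      adolescent = c(11.0, 17.9),
                      adult = c(18.6, 32.0)),
    p_male = c(child = 0.94, adolescent = 0.82, adult = 0.78),
    fiq = list(child = list(ASD = c(110.6, 19.9), TC = c(112.2, 12.3)),
               adolescent = list(ASD = c(103.6, 15.5), TC = c(104.3, 13.5)),
               adult = list(ASD = c(108.1, 13.9), TC = c(110.1, 7.9)))) {
  cohorts <- c("child", "adolescent", "adult")
  if (!identical(names(cell_sizes), cohorts))
    stop("cell_sizes must be named child, adolescent, adult (in order)")
  counts <- unlist(cell_sizes)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("configuration error: every design cell needs a positive integer count")
  lims <- do.call(rbind, age_ranges[cohorts])
  if (any(lims[, 1] >= lims[, 2]) || any(diff(as.vector(t(lims))) <= 0))
    stop("age intervals must be ordered and disjoint")
  structure(list(cell_sizes = cell_sizes, age_ranges = age_ranges,
                 p_male = p_male, fiq = fiq),
            class = "cohort_spec")
}

#' Generate a phenotype table
#'
#' Draws one record per subject: diagnosis, cohort, age uniform within the
#' cohort interval (resampled until every age lies within 3 SD of its cohort
#' mean), gender and FIQ per the cell distributions. ADOS subscores are left
#' missing; [generate_symptoms()] fills them for ASD subjects from the
#' planted regional amplitudes. Deterministic given the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Phenotype `data.frame` (one row per subject).
#' @export
generate_phenotypes <- function(spec = cohort_spec(), seed = 1) {
  with_seed(seed, {
    rows <- list()
    i <- 0
    for (cohort in names(spec$cell_sizes)) {
      rng <- spec$age_ranges[[cohort]]
      for (diag in c("ASD", "TC")) {
        n <- spec$cell_sizes[[cohort]][[diag]]
        rows[[paste(cohort, diag)]] <- data.frame(
          subject_id = sprintf("sub%04d", i + seq_len(n)),
          diagnosis = diag, cohort = cohort,
          age_years = stats::runif(n, rng[1], rng[2]),
          gender = stats::rbinom(n, 1, spec$p_male[[cohort]]),
          fiq = stats::rnorm(n, spec$fiq[[cohort]][[diag]][1],
                             spec$fiq[[cohort]][[diag]][2]),
          stringsAsFactors = FALSE)
        i <- i + n
      }
    }
    ph <- do.call(rbind, rows)
    rownames(ph) <- NULL
    # ages restricted to within 3 SD of the cohort mean; resample violators
    for (cohort in names(spec$cell_sizes)) {
      idx <- which(ph$cohort == cohort)
      rng <- spec$age_ranges[[cohort]]
      repeat {
        a <- ph$age_years[idx]
        bad <- abs(a - mean(a)) > 3 * stats::sd(a)
        if (!any(bad)) break
        ph$age_years[idx[bad]] <- stats::runif(sum(bad), rng[1], rng[2])
      }
    }
    ph$diagnosis <- factor(ph$diagnosis, levels = c("ASD", "TC"))
    ph$cohort <- factor(ph$cohort, levels = c("child", "adolescent", "adult"))
    ph$ados_comm <- NA_real_
    ph$ados_social <- NA_real_
    ph$ados_stereo <- NA_real_
    ph
  })
}

#' Planted regional effect
#'
#' A spherical voxel set with a per-diagnosis quadratic amplitude model
#' `b0 + b1 * age + b2 * age^2` giving the oscillation amplitude (root mean
#' square, in background-noise SD units) planted in the region. Constant
#' group offsets are the special case `b1 = b2 = 0`.
#'
#' @param name Region label (e.g. "mPFC").
#' @param center Sphere centre, 1-based voxel coordinates.
#' @param radius Sphere radius in voxels.
#' @param coef List with elements `ASD` and `TC`, each `c(b0, b1, b2)`.
#' @param noise_sd SD of the multiplicative between-subject amplitude jitter.
#' @return An object of class `region_effect`.
#' @export
region_effect <- function(name, center, radius, coef, noise_sd = 0.18) {
  stopifnot(length(center) == 3, radius > 0,
            all(c("ASD", "TC") %in% names(coef)))
  ages <- seq(5, 45, by = 0.5)
  for (g in c("ASD", "TC")) {
    b <- coef[[g]]
    if (length(b) != 3) stop("coef$", g, " must be c(b0, b1, b2)")
    if (any(b[1] + b[2] * ages + b[3] * ages^2 <= 0))
      stop("amplitude model for ", name, "/", g,
           " is not strictly positive over ages 5-45")
  }
  structure(list(name = name, center = center, radius = radius,
                 coef = coef, noise_sd = noise_sd),
            class = "region_effect")
}

amplitude_value <- function(region, diagnosis, age) {
  b <- region$coef[[as.character(diagnosis)]]
  b[1] + b[2] * age + b[3] * age^2
}

sphere_mask <- function(grid_dims, center, radius) {
  g <- expand.grid(x = seq_len(grid_dims[1]), y = seq_len(grid_dims[2]),
                   z = seq_len(grid_dims[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, grid_dims)
}

ellipsoid_mask <- function(grid_dims, center, semi) {
  g <- expand.grid(x = seq_len(grid_dims[1]), y = seq_len(grid_dims[2]),
                   z = seq_len(grid_dims[3]))
  v <- ((g$x - center[1]) / semi[1])^2 + ((g$y - center[2]) / semi[2])^2 +
    ((g$z - center[3]) / semi[3])^2
  array(v <= 1, grid_dims)
}

#' Default planted regions
#'
#' Three spherical regions on the default grid, emulating the reported
#' effect topography: a medial-prefrontal (mPFC) region carrying the
#' diagnosis-by-age interaction (quadratic amplitude over age in TC, flat in
#' ASD), and precuneus and middle-occipital (MOG) regions carrying a
#' constant ASD-lower diagnosis effect at all ages.
#'
#' @param grid_dims Simulation grid dimensions.
#' @return Named list of [region_effect()] objects.
#' @export
default_regions <- function(grid_dims = c(22, 26, 22)) {
  # TC mPFC amplitude 0.58 + 0.00105 (age - 27)^2: ~0.90 at 9 y, 0.76 at
  # 14 y, 0.58 at 27 y -> higher in children than adolescents/adults, while
  # the ASD trajectory is flat. Contrasts are sized so the in-region
  # interaction Z sits near 4-4.5: high enough that the cluster is detected
  # in essentially every realization, low enough that the smoothing halo
  # around the region stays below the Z > 2.33 cluster-forming threshold.
  tc_mpfc <- c(0.58 + 0.00105 * 27^2, -2 * 0.00105 * 27, 0.00105)
  list(
    mPFC = region_effect("mPFC", center = c(12, 22, 14), radius = 2.8,
                         coef = list(TC = tc_mpfc, ASD = c(0.76, 0, 0))),
    precuneus = region_effect("precuneus", center = c(12, 5, 14), radius = 2.2,
                              coef = list(TC = c(0.90, 0, 0), ASD = c(0.78, 0, 0))),
    MOG = region_effect("MOG", center = c(7, 7, 11), radius = 2.1,
                        coef = list(TC = c(0.90, 0, 0), ASD = c(0.78, 0, 0)))
  )
}

#' Simulation configuration
#'
#' Collects the acquisition constants (TR 2 s, 180 volumes, 0.01-0.08 Hz
#' band), the simulation grid, the planted regions, the symptom-coupling
#' model and the motion random-walk model, and builds the brain / white
#' matter / CSF masks.
#'
#' Oscillations are sums of `n_sinusoids` random sinusoids whose frequencies
#' sit exactly on the in-band DFT bins of a series of length `freq_grid_n`
#' (default `n_volumes - 10`, the post-discard length), so the planted
#' amplitude has a closed-form relation to ALFF.
#'
#' @param grid_dims Grid size (default `c(22, 26, 22)`).
#' @param voxel_size_mm Voxel size in mm (default 3).
#' @param tr_s Repetition time in seconds (default 2).
#' @param n_volumes Number of volumes (default 180).
#' @param band_hz Oscillation band in Hz (default `c(0.01, 0.08)`).
#' @param background_sd In-brain white-noise SD (default 1).
#' @param n_sinusoids Sinusoids per regional oscillation (default 5).
#' @param freq_grid_n DFT grid length defining admissible frequencies.
#' @param regions Named list of [region_effect()]s.
#' @param symptom_coupling List: `weights` (per region), `intercept`,
#'   `noise_sd`, `range` mapping summed regional amplitude to ADOS social.
#' @param motion_step_sd Random-walk step SDs, `c(trans = mm, rot = radians)`.
#' @return An object of class `simulation_config` (includes `brain_mask`,
#'   `wm_mask`, `csf_mask` and per-region voxel sets).
#' @export
simulation_config <- function(grid_dims = c(22, 26, 22),
                              voxel_size_mm = c(3, 3, 3),
                              tr_s = 2, n_volumes = 180,
                              band_hz = c(0.01, 0.08),
                              background_sd = 1,
                              n_sinusoids = 5,
                              freq_grid_n = n_volumes - 10,
                              regions = default_regions(grid_dims),
                              symptom_coupling = list(
                                weights = c(mPFC = 10, precuneus = 10, MOG = 10),
                                intercept = -15.4, noise_sd = 1.0,
                                range = c(0, 14)),
                              motion_step_sd = c(trans = 0.03, rot = 3e-4)) {
  nyq <- 1 / (2 * tr_s)
  if (!(0 < band_hz[1] && band_hz[1] < band_hz[2] && band_hz[2] < nyq))
    stop("band must satisfy 0 < low < high < Nyquist")
  if (n_volumes <= 10) stop("n_volumes must exceed the discard count")
  ctr <- (grid_dims + 1) / 2
  brain <- ellipsoid_mask(grid_dims, ctr, grid_dims * c(0.43, 0.46, 0.43))
  # tissue spheres sit well away from every planted region so that the
  # smoothed regional oscillations cannot leak into the nuisance regressors
  wm <- sphere_mask(grid_dims, pmax(round(ctr + grid_dims * c(0.2, 0.02, -0.2)), 1),
                    2.5) & brain
  csf <- sphere_mask(grid_dims, pmax(round(ctr + grid_dims * c(-0.25, 0.02, 0.2)), 1),
                     2.0) & brain
  if (!any(wm) || !any(csf))
    stop("tissue masks are empty on this grid; use a larger grid")
  for (r in names(regions)) {
    vox <- sphere_mask(grid_dims, regions[[r]]$center, regions[[r]]$radius)
    if (any(vox & !brain))
      stop("region ", r, " lies partly outside the brain mask")
    if (any(vox & (wm | csf)))
      stop("region ", r, " overlaps a tissue mask")
    regions[[r]]$voxel_set <- vox
  }
  structure(list(grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
                 tr_s = tr_s, n_volumes = n_volumes, band_hz = band_hz,
                 background_sd = background_sd, n_sinusoids = n_sinusoids,
                 freq_grid_n = freq_grid_n, regions = regions,
                 symptom_coupling = symptom_coupling,
                 motion_step_sd = motion_step_sd,
                 brain_mask = brain, wm_mask = wm, csf_mask = csf),
            class = "simulation_config")
}

#' Per-subject planted regional amplitudes
#'
#' Evaluates each region's amplitude model at the subject's diagnosis and
#' age and applies multiplicative jitter `1 + e`, `e ~ N(0, noise_sd)`
#' truncated to +/- 0.5 (amplitudes stay strictly positive).
#'
#' @param phenotypes Phenotype table.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return n x n_regions matrix of amplitudes.
#' @export
subject_amplitudes <- function(phenotypes, config, seed = 1) {
  with_seed(seed, {
    n <- nrow(phenotypes)
    out <- matrix(NA_real_, n, length(config$regions),
                  dimnames = list(phenotypes$subject_id, names(config$regions)))
    for (r in names(config$regions)) {
      reg <- config$regions[[r]]
      base <- mapply(amplitude_value, diagnosis = phenotypes$diagnosis,
                     age = phenotypes$age_years,
                     MoreArgs = list(region = reg))
      jit <- pmin(pmax(stats::rnorm(n, 0, reg$noise_sd), -0.5), 0.5)
      out[, r] <- base * (1 + jit)
    }
    out
  })
}

#' Generate a rigid-body motion trace
#'
#' Gaussian random walk starting at zero: increments in each of the 3
#' translations (mm) and 3 rotations (radians) are independent draws with
#' the configured step SDs. Motion-outlier subjects additionally receive a
#' deterministic 4 mm linear drift in x, guaranteeing breach of the 3 mm
#' exclusion limit.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param outlier Plant a gross-motion breach (default FALSE).
#' @return A [motion_trace()] with `config$n_volumes` rows.
#' @export
generate_motion_trace <- function(config, seed = 1, outlier = FALSE) {
  nt <- config$n_volumes
  if (nt < 2) stop("need at least 2 volumes")
  with_seed(seed, {
    sd6 <- rep(config$motion_step_sd[c("trans", "rot")], each = 3)
    steps <- matrix(stats::rnorm(6 * (nt - 1), 0, rep(sd6, each = nt - 1)),
                    nt - 1, 6)
    p <- rbind(0, apply(steps, 2, cumsum))
    if (outlier) p[, 1] <- p[, 1] + seq(0, 4, length.out = nt)
    motion_trace(p, tr = config$tr_s)
  })
}

#' Generate one subject's 4D volume
#'
#' In-brain voxels receive white noise of the configured SD; each region
#' additionally receives a spatially coherent band-limited oscillation
#' (sum of `n_sinusoids` equal-amplitude sinusoids on random in-band DFT
#' bins with random phases, scaled to the subject's regional amplitude as
#' root mean square). Out-of-brain voxels are zero.
#'
#' @param record One-row phenotype record (diagnosis, age).
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param amplitudes Optional named amplitude vector (one per region), e.g.
#'   a row of [subject_amplitudes()]; if omitted, amplitudes are drawn here.
#' @return A [volume4d()].
#' @export
generate_subject_volume <- function(record, config, seed = 1,
                                    amplitudes = NULL) {
  if (is.null(amplitudes)) {
    amplitudes <- drop(subject_amplitudes(record, config, seed = subseed(seed, 1)))
    names(amplitudes) <- names(config$regions)
  }
  gd <- config$grid_dims
  nt <- config$n_volumes
  brain <- config$brain_mask
  with_seed(subseed(seed, 2), {
    flat <- matrix(0, prod(gd), nt)
    nb <- sum(brain)
    flat[as.logical(brain), ] <- stats::rnorm(nb * nt, 0, config$background_sd)
    tt <- (0:(nt - 1)) * config$tr_s
    for (r in names(config$regions)) {
      osc <- band_limited_oscillation(
        tt, config$freq_grid_n, config$tr_s, config$band_hz,
        config$n_sinusoids, amplitudes[[r]])
      vox <- which(config$regions[[r]]$voxel_set)
      flat[vox, ] <- flat[vox, ] + rep(osc, each = length(vox))
    }
    volume4d(array(flat, c(gd, nt)), config$voxel_size_mm, config$tr_s)
  })
}

# Sum of K equal-amplitude sinusoids on distinct in-band DFT bins of an
# n_grid-point series; scaled so the (infinite-sample) RMS equals `rms`.
band_limited_oscillation <- function(times, n_grid, tr_s, band_hz, K, rms) {
  f_all <- (1:floor(n_grid / 2)) / (n_grid * tr_s)
  f_in <- f_all[f_all >= band_hz[1] & f_all <= band_hz[2]]
  if (length(f_in) < K)
    stop("fewer than ", K, " DFT bins inside the oscillation band")
  f <- sample(f_in, K)
  phi <- stats::runif(K, 0, 2 * pi)
  x <- rowSums(sin(outer(times, 2 * pi * f) +
                     matrix(phi, length(times), K, byrow = TRUE)))
  rms * sqrt(2 / K) * x
}

#' Generate ADOS symptom scores
#'
#' ADOS social for ASD subjects is a linear combination of the subject's
#' planted regional amplitudes plus Gaussian noise, rounded and clipped into
#' the configured integer range. Communication and stereotyped-behavior
#' subscores are drawn independently (no planted coupling). TC subjects keep
#' missing scores.
#'
#' @param phenotypes Phenotype table.
#' @param amplitudes Matrix from [subject_amplitudes()] (rows match subjects).
#' @param coupling Coupling list (see [simulation_config()]).
#' @param seed Integer seed.
#' @return Phenotype table with ADOS columns filled for ASD.
#' @export
generate_symptoms <- function(phenotypes, amplitudes,
                              coupling = simulation_config()$symptom_coupling,
                              seed = 1) {
  asd <- which(phenotypes$diagnosis == "ASD")
  if (!length(asd)) return(phenotypes)
  w <- coupling$weights
  A <- amplitudes[asd, names(w), drop = FALSE]
  with_seed(seed, {
    raw <- coupling$intercept + drop(A %*% w) +
      stats::rnorm(length(asd), 0, coupling$noise_sd)
    rg <- coupling$range
    phenotypes$ados_social[asd] <- pmin(pmax(round(raw), rg[1]), rg[2])
    phenotypes$ados_comm[asd] <-
      pmin(pmax(round(stats::rnorm(length(asd), 3.5, 1.6)), 0), 8)
    phenotypes$ados_stereo[asd] <-
      pmin(pmax(round(stats::rnorm(length(asd), 2.2, 1.5)), 0), 8)
  })
  phenotypes
}

#' Generate a full candidate roster with planted exclusions
#'
#' Builds the 128-subject core cohort plus `n_unmatched` covariate-unmatched
#' extras (ages drawn over the whole 6-40 y span, flagged `matched = FALSE`)
#' and `n_motion` subjects flagged to receive gross-motion traces, for a
#' default total of 184 candidates. [cohort_filter()] applies the exclusion
#' rules to recover the analysis sample.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param n_unmatched Number of planted matching failures (default 49).
#' @param n_motion Number of planted gross-motion subjects (default 7).
#' @return Phenotype table with logical columns `matched` and `motion_outlier`.
#' @export
generate_roster <- function(spec = cohort_spec(), seed = 1,
                            n_unmatched = 49, n_motion = 7) {
  core <- generate_phenotypes(spec, seed)
  core$matched <- TRUE
  core$motion_outlier <- FALSE
  with_seed(subseed(seed, 3), {
    extras <- data.frame(
      subject_id = sprintf("subx%03d", seq_len(n_unmatched + n_motion)),
      diagnosis = factor(rep_len(c("ASD", "TC"), n_unmatched + n_motion),
                         levels = c("ASD", "TC")),
      cohort = factor(NA, levels = levels(core$cohort)),
      age_years = stats::runif(n_unmatched + n_motion, 6, 40),
      gender = stats::rbinom(n_unmatched + n_motion, 1, 0.85),
      fiq = stats::rnorm(n_unmatched + n_motion, 105, 15),
      ados_comm = NA_real_, ados_social = NA_real_, ados_stereo = NA_real_,
      matched = rep(c(FALSE, TRUE), c(n_unmatched, n_motion)),
      motion_outlier = rep(c(FALSE, TRUE), c(n_unmatched, n_motion)),
      stringsAsFactors = FALSE)
    extras$cohort <- age_to_cohort(extras$age_years)
    rbind(core, extras)
  })
}

#' Apply the cohort exclusion rules
#'
#' Drops subjects whose motion trace breaches the 3 mm / 3 degree rule,
#' subjects flagged as failing diagnostic-group matching, and (iteratively)
#' subjects whose age falls more than 3 SD from their cohort mean.
#'
#' @param roster Table from [generate_roster()].
#' @param traces List of [motion_trace()]s, one per roster row.
#' @return The filtered phenotype table; attribute `n_excluded` records the
#'   counts per rule.
#' @export
cohort_filter <- function(roster, traces) {
  stopifnot(length(traces) == nrow(roster))
  motion_excl <- vapply(traces, motion_exclusion, logical(1))
  keep <- !motion_excl & roster$matched
  out <- roster[keep, , drop = FALSE]
  n_age <- 0
  repeat {
    bad <- logical(nrow(out))
    for (cohort in levels(out$cohort)) {
      idx <- which(out$cohort == cohort)
      if (length(idx) < 3) next
      a <- out$age_years[idx]
      bad[idx] <- abs(a - mean(a)) > 3 * stats::sd(a)
    }
    if (!any(bad)) break
    n_age <- n_age + sum(bad)
    out <- out[!bad, , drop = FALSE]
  }
  attr(out, "n_excluded") <- c(motion = sum(motion_excl),
                               matching = sum(!roster$matched & !motion_excl),
                               age_3sd = n_age)
  out
}

#' Generate a complete synthetic dataset
#'
#' Phenotypes, per-subject planted amplitudes, ADOS scores, motion traces
#' and (optionally) the 4D volumes. With `dir` set, every artifact is
#' written to disk (NIfTI-1 volumes and masks, motion text files, phenotype
#' TSV and a JSON manifest with seed and checksums) and volumes are not kept
#' in memory; use this for full-size cohorts.
#'
#' @param config A [simulation_config()].
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed (all stage seeds derive from it).
#' @param dir Optional output directory.
#' @param keep_volumes Keep generated volumes in memory (default: only when
#'   `dir` is NULL).
#' @return List with `phenotypes` (including `mean_fd`), `amplitudes`,
#'   `traces`, `volumes` (or NULL), `config`, `seed` and, when written,
#'   `manifest`.
#' @export
generate_dataset <- function(config = simulation_config(),
                             spec = cohort_spec(), seed = 1, dir = NULL,
                             keep_volumes = is.null(dir)) {
  ph <- generate_phenotypes(spec, seed)
  amps <- subject_amplitudes(ph, config, subseed(seed, 10))
  ph <- generate_symptoms(ph, amps, config$symptom_coupling, subseed(seed, 11))
  n <- nrow(ph)
  traces <- lapply(seq_len(n), function(i)
    generate_motion_trace(config, subseed(seed, 20, i)))
  ph$mean_fd <- vapply(traces, function(m)
    framewise_displacement(m)$mean_fd, numeric(1))
  volumes <- if (keep_volumes) vector("list", n) else NULL
  files <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_mask(config$brain_mask, file.path(dir, "brain_mask.nii.gz"),
               config$voxel_size_mm)
    write_mask(config$wm_mask, file.path(dir, "wm_mask.nii.gz"),
               config$voxel_size_mm)
    write_mask(config$csf_mask, file.path(dir, "csf_mask.nii.gz"),
               config$voxel_size_mm)
    write_phenotypes(ph, file.path(dir, "phenotypes.tsv"))
    files <- c("brain_mask.nii.gz", "wm_mask.nii.gz", "csf_mask.nii.gz",
               "phenotypes.tsv")
  }
  for (i in seq_len(n)) {
    vol <- generate_subject_volume(ph[i, ], config, subseed(seed, 30, i),
                                   amplitudes = amps[i, ])
    if (keep_volumes) volumes[[i]] <- vol
    if (!is.null(dir)) {
      vf <- sprintf("%s_bold.nii.gz", ph$subject_id[i])
      mf <- sprintf("%s_motion.txt", ph$subject_id[i])
      write_volume(vol, file.path(dir, vf))
      write_motion(traces[[i]], file.path(dir, mf))
      files <- c(files, vf, mf)
    }
  }
  out <- list(phenotypes = ph, amplitudes = amps, traces = traces,
              volumes = volumes, config = config, seed = seed)
  if (!is.null(dir)) {
    out$manifest <- write_manifest(config, seed, dir, files)
  }
  out
}

#' Write an in-memory dataset to a directory
#'
#' @param dataset List from [generate_dataset()] with volumes kept.
#' @param dir Output directory.
#' @return The manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (is.null(dataset$volumes)) stop("dataset has no in-memory volumes")
  config <- dataset$config
  ph <- dataset$phenotypes
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mask(config$brain_mask, file.path(dir, "brain_mask.nii.gz"),
             config$voxel_size_mm)
  write_mask(config$wm_mask, file.path(dir, "wm_mask.nii.gz"),
             config$voxel_size_mm)
  write_mask(config$csf_mask, file.path(dir, "csf_mask.nii.gz"),
             config$voxel_size_mm)
  write_phenotypes(ph, file.path(dir, "phenotypes.tsv"))
  files <- c("brain_mask.nii.gz", "wm_mask.nii.gz", "csf_mask.nii.gz",
             "phenotypes.tsv")
  for (i in seq_len(nrow(ph))) {
    vf <- sprintf("%s_bold.nii.gz", ph$subject_id[i])
    mf <- sprintf("%s_motion.txt", ph$subject_id[i])
    write_volume(dataset$volumes[[i]], file.path(dir, vf))
    write_motion(dataset$traces[[i]], file.path(dir, mf))
    files <- c(files, vf, mf)
  }
  invisible(write_manifest(config, dataset$seed, dir, files))
}

write_manifest <- function(config, seed, dir, files) {
  manifest <- list(
    seed = seed,
    config = list(grid_dims = config$grid_dims,
                  voxel_size_mm = config$voxel_size_mm,
                  tr_s = config$tr_s, n_volumes = config$n_volumes,
                  band_hz = config$band_hz,
                  background_sd = config$background_sd,
                  n_sinusoids = config$n_sinusoids,
                  freq_grid_n = config$freq_grid_n,
                  regions = lapply(config$regions, function(r)
                    r[c("name", "center", "radius", "coef", "noise_sd")]),
                  symptom_coupling = config$symptom_coupling,
                  motion_step_sd = as.list(config$motion_step_sd)),
    files = files,
    checksums = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

# Deterministic sub-seed derivation (stays inside 32-bit integer range).
subseed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (v in c(...)) x <- (x * 69621 + as.double(v) * 1013 + 1) %% 2147483647
  as.integer(x)
}

# Evaluate an expression with a temporary RNG state; restores any prior state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
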