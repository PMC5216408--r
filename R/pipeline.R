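#' Run configuration for the full analysis pipeline
#'
#' Collects every constant of the analysis in one serializable object:
#' simulation and cohort settings, preprocessing parameters, the voxel- and
#' cluster-level thresholds, the post-hoc family size, SVR hyperparameters
#' and the per-stage seeds (all derived from one master seed).
#'
#' @param sim A [simulation_config()].
#' @param cohort A [cohort_spec()].
#' @param seed Master integer seed.
#' @param discard Initial volumes to drop (default 10).
#' @param fwhm_mm Smoothing FWHM in mm (default 8).
#' @param band Pass band in Hz (default `c(0.01, 0.08)`).
#' @param trans_mm,rot_deg Gross-motion limits (3 mm / 3 degrees).
#' @param voxel_p Voxel-level (cluster-forming) p threshold (default 0.01,
#'   i.e. Z > 2.33 one-tailed).
#' @param cluster_alpha Cluster-level familywise alpha (default 0.05).
#' @param connectivity Cluster connectivity, 6 or 26 (default 6).
#' @param n_perm Permutations for the prediction test (default 1000).
#' @param svr_c,svr_epsilon Linear-SVR cost and insensitivity (1 and 0.1).
#' @param svr_tol Solver stopping tolerance used inside the permutation
#'   loops (default 1e-2; see [svr_linear()]).
#' @param out_dir Optional artifact directory.
#' @param verbose Print stage progress (default FALSE).
#' @return A `run_config` list.
#' @export
run_config <- function(sim = simulation_config(), cohort = cohort_spec(),
                       seed = 1, discard = 10, fwhm_mm = 8,
                       band = c(0.01, 0.08), trans_mm = 3, rot_deg = 3,
                       voxel_p = 0.01, cluster_alpha = 0.05,
                       connectivity = 6, n_perm = 1000,
                       svr_c = 1, svr_epsilon = 0.1, svr_tol = 1e-2,
                       out_dir = NULL, verbose = FALSE) {
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_alpha > 0, cluster_alpha < 1,
            n_perm >= 1, svr_c > 0, svr_epsilon >= 0,
            connectivity %in% c(6, 26), discard >= 0,
            fwhm_mm >= 0, band[1] > 0, band[1] < band[2])
  structure(list(sim = sim, cohort = cohort, seed = seed, discard = discard,
                 fwhm_mm = fwhm_mm, band = band, trans_mm = trans_mm,
                 rot_deg = rot_deg, voxel_p = voxel_p,
                 cluster_alpha = cluster_alpha, connectivity = connectivity,
                 n_perm = n_perm, svr_c = svr_c, svr_epsilon = svr_epsilon,
                 svr_tol = svr_tol, out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

#' Simulate a cohort and compute its standardized ALFF maps
#'
#' Streams subjects one at a time (generate volume, preprocess, ALFF,
#' standardize) so the full cohort's 4D data never has to be held in
#' memory. Mean framewise displacement is recomputed on the post-discard
#' motion trace and stored as the `mean_fd` covariate.
#'
#' @param config A [run_config()].
#' @return List: `phenotypes`, `amplitudes`, `Y` (subjects x in-mask voxels
#'   standardized ALFF), `mask`, `config`.
#' @export
simulate_alff_cohort <- function(config = run_config()) {
  sim <- config$sim
  seed <- config$seed
  ph <- generate_phenotypes(config$cohort, seed)
  amps <- subject_amplitudes(ph, sim, subseed(seed, 10))
  ph <- generate_symptoms(ph, amps, sim$symptom_coupling, subseed(seed, 11))
  n <- nrow(ph)
  mask <- sim$brain_mask
  Y <- matrix(NA_real_, n, sum(mask),
              dimnames = list(ph$subject_id, NULL))
  ph$mean_fd <- NA_real_
  for (i in seq_len(n)) {
    if (config$verbose && i %% 16 == 1)
      message("  subject ", i, "/", n)
    motion <- generate_motion_trace(sim, subseed(seed, 20, i))
    vol <- generate_subject_volume(ph[i, ], sim, subseed(seed, 30, i),
                                   amplitudes = amps[i, ])
    pp <- preprocess_subject(vol, motion, mask, sim$wm_mask, sim$csf_mask,
                             discard = config$discard,
                             fwhm_mm = config$fwhm_mm, band = config$band,
                             trans_mm = config$trans_mm,
                             rot_deg = config$rot_deg)
    ph$mean_fd[i] <- pp$mean_fd
    map <- standardize_global_mean(
      compute_alff_map(pp$vol, mask, config$band))
    Y[i, ] <- map$values[as.logical(mask)]
  }
  list(phenotypes = ph, amplitudes = amps, Y = Y, mask = mask,
       config = config)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, ALFF, group inference (ANCOVA + GRF
#' cluster correction + post-hoc t-tests), trajectory modelling on the
#' interaction region and SVR symptom prediction for the three ADOS
#' subscales, and optionally writes a machine-readable summary.
#'
#' @param config A [run_config()].
#' @return Object of class `alffdev_run` with elements `phenotypes`,
#'   `design`, `stats` (per-effect `stat_map`s), `smoothness`,
#'   `z_threshold`, `extent_threshold`, `clusters` (per effect),
#'   `posthoc`, `trajectory`, `prediction` (one `prediction_result` per
#'   subscale), `config`.
#' @export
run_all <- function(config = run_config()) {
  timings <- numeric(0)
  stage <- function(name, expr) {
    if (config$verbose) message("[", name, "]")
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- unname(proc.time()[3] - t0)
    out
  }
  sim <- stage("simulate", simulate_alff_cohort(config))
  ph <- sim$phenotypes
  mask <- sim$mask
  design <- stage("design", build_design(ph))
  stats_maps <- stage("ancova", voxelwise_ancova(sim$Y, design, mask))
  smooth <- stage("smoothness",
                  estimate_smoothness(stats_maps$residuals, mask,
                                      config$sim$voxel_size_mm))
  z_thr <- stats::qnorm(config$voxel_p, lower.tail = FALSE)
  k <- stage("grf", grf_extent_threshold(z_thr, smooth, mask,
                                         config$cluster_alpha))
  clusters <- stage("clusters", {
    lapply(stats_maps[c("diagnosis", "interaction")], function(sm)
      extract_clusters(sm, z_thr, k, config$connectivity, mask, smooth))
  })
  posthoc <- stage("posthoc", {
    lapply(clusters$diagnosis$voxels, function(co) {
      roi <- roi_means(sim$Y, mask, co)
      posthoc_ttests(roi, ph)
    })
  })
  trajectory <- stage("trajectory", {
    if (!length(clusters$interaction$voxels)) NULL else {
      co <- do.call(rbind, clusters$interaction$voxels)
      roi <- roi_means(sim$Y, mask, co)
      tc <- ph$diagnosis == "TC"
      fit_tc <- fit_quadratic(ph$age_years[tc], roi[tc], "TC")
      fit_asd <- fit_quadratic(ph$age_years[!tc], roi[!tc], "ASD")
      list(tc = fit_tc, asd = fit_asd,
           report = compare_group_trajectories(fit_tc, fit_asd))
    }
  })
  prediction <- stage("prediction", {
    pooled <- c(clusters$diagnosis$voxels, clusters$interaction$voxels)
    if (!length(pooled)) NULL else {
      out <- list()
      for (target in c("ados_comm", "ados_social", "ados_stereo")) {
        fm <- build_feature_matrix(sim$Y, mask, pooled, ph, target)
        out[[target]] <- permutation_test(
          fm$X, fm$y, n_perm = config$n_perm,
          seed = subseed(config$seed, 40, match(target, c(
            "ados_comm", "ados_social", "ados_stereo"))),
          C = config$svr_c, epsilon = config$svr_epsilon,
          tol = config$svr_tol, target = target)
      }
      out
    }
  })
  run <- structure(list(phenotypes = ph, amplitudes = sim$amplitudes,
                        Y = sim$Y, mask = mask, design = design,
                        stats = stats_maps[c("diagnosis", "age", "interaction")],
                        residuals = stats_maps$residuals,
                        smoothness = smooth, z_threshold = z_thr,
                        extent_threshold = k, clusters = clusters,
                        posthoc = posthoc, trajectory = trajectory,
                        prediction = prediction, config = config,
                        timings = timings),
                   class = "alffdev_run")
  if (!is.null(config$out_dir)) stage("write", write_run(run, config$out_dir))
  run
}

# Per-subject mean over an ROI given cluster coordinates.
roi_means <- function(Y, mask, coords) {
  gd <- dim(mask)
  lin <- coords[, 1] + (coords[, 2] - 1) * gd[1] + (coords[, 3] - 1) * gd[1] * gd[2]
  cols <- match(lin, which(as.logical(mask)))
  rowMeans(Y[, cols, drop = FALSE])
}

#' @export
print.alffdev_run <- function(x, ...) {
  cat("<alffdev_run>\n")
  cat(sprintf("  %d subjects, %d in-mask voxels\n",
              nrow(x$phenotypes), ncol(x$Y)))
  cat(sprintf("  voxel Z > %.3f, extent >= %d voxels (FWHM %s vox)\n",
              x$z_threshold, x$extent_threshold,
              paste(sprintf("%.2f", x$smoothness$fwhm_voxels), collapse = "x")))
  for (eff in names(x$clusters))
    cat(sprintf("  %s: %d significant cluster(s)\n", eff,
                nrow(x$clusters[[eff]]$table)))
  if (!is.null(x$trajectory))
    cat(sprintf("  trajectory p: TC %.4g, ASD %.4g\n",
                x$trajectory$tc$p_value, x$trajectory$asd$p_value))
  if (!is.null(x$prediction))
    for (p in x$prediction)
      cat(sprintf("  prediction %s: R = %.3f, p_perm = %.4g\n",
                  p$target, p$r, p$p_perm))
  invisible(x)
}

#' Summarize a pipeline run as a plain list (JSON-ready)
#'
#' @param object An `alffdev_run`.
#' @param ... Unused.
#' @return Nested list with seeds, thresholds, cluster tables, trajectory
#'   fits and prediction results.
#' @export
summary.alffdev_run <- function(object, ...) {
  x <- object
  list(
    seed = x$config$seed,
    n_subjects = nrow(x$phenotypes),
    n_voxels = ncol(x$Y),
    design = list(df = as.list(x$design$df), df_error = x$design$df_error),
    smoothness = list(fwhm_voxels = x$smoothness$fwhm_voxels,
                      fwhm_mm = x$smoothness$fwhm_mm,
                      resels = x$smoothness$resels),
    thresholds = list(z = x$z_threshold, extent = x$extent_threshold,
                      voxel_p = x$config$voxel_p,
                      cluster_alpha = x$config$cluster_alpha),
    clusters = lapply(x$clusters, function(cs) cs$table),
    posthoc = x$posthoc,
    trajectory = if (is.null(x$trajectory)) NULL else
      x$trajectory$report$table,
    prediction = if (is.null(x$prediction)) NULL else
      lapply(x$prediction, function(p)
        list(target = p$target, r = p$r, p_perm = p$p_perm, n = p$n,
             n_perm = p$n_perm)))
}

# Write maps, cluster tables and the summary JSON to a directory.
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- run$config$sim$voxel_size_mm
  for (eff in names(run$stats)) {
    sm <- run$stats[[eff]]
    for (what in c("F", "Z", "partial_eta2")) {
      img <- RNifti::asNifti(sm[[what]])
      RNifti::pixdim(img) <- vs
      RNifti::writeNifti(img, file.path(dir, sprintf("%s_%s.nii.gz", eff, what)))
    }
  }
  for (eff in names(run$clusters))
    utils::write.table(run$clusters[[eff]]$table,
                       file.path(dir, sprintf("clusters_%s.tsv", eff)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$trajectory))
    utils::write.table(run$trajectory$report$table,
                       file.path(dir, "trajectory_fits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$prediction)) {
    pred_tab <- do.call(rbind, lapply(run$prediction, function(p)
      data.frame(target = p$target, subject = seq_along(p$observed),
                 observed = p$observed, predicted = p$predicted)))
    utils::write.table(pred_tab, file.path(dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_phenotypes(run$phenotypes, file.path(dir, "phenotypes.tsv"))
  jsonlite::write_json(summary(run), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
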