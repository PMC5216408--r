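#' Build the diagnosis-by-age ANCOVA design matrix
#'
#' Sum-to-zero (effects) coding for the two factors, mirroring the factorial
#' convention of statistical parametric mapping: intercept, 1 diagnosis
#' column, 2 age-cohort columns, 2 interaction columns, plus mean-centered
#' gender, FIQ and mean-FD covariates (9 columns for the default cohort,
#' error df `n - 9`).
#'
#' @param phenotypes Phenotype table with `diagnosis`, `cohort`, `gender`,
#'   `fiq`, `mean_fd` (covariates may be dropped via `covariates`).
#' @param covariates Character vector of covariate columns to include.
#' @return An object of class `alff_design`: list with the matrix `X`,
#'   per-effect column indices, `df` per effect and `df_error`.
#' @export
build_design <- function(phenotypes,
                         covariates = c("gender", "fiq", "mean_fd")) {
  ph <- phenotypes
  ph$diagnosis <- droplevels(factor(ph$diagnosis))
  ph$cohort <- droplevels(factor(ph$cohort))
  if (nlevels(ph$diagnosis) != 2)
    stop("both diagnosis levels must be present")
  if (nlevels(ph$cohort) != 3)
    stop("all three age cohorts must be present")
  for (cv in covariates) {
    if (is.null(ph[[cv]])) stop("missing covariate column: ", cv)
    if (anyNA(ph[[cv]])) stop("missing values in covariate: ", cv)
  }
  D <- stats::model.matrix(~ diagnosis, ph,
                           contrasts.arg = list(diagnosis = "contr.sum"))[, 2, drop = FALSE]
  A <- stats::model.matrix(~ cohort, ph,
                           contrasts.arg = list(cohort = "contr.sum"))[, 2:3, drop = FALSE]
  X <- cbind(intercept = 1, diagnosis = D,
             A, D[, 1] * A)
  colnames(X) <- c("intercept", "diagnosis", "age1", "age2",
                   "diagnosis_age1", "diagnosis_age2")
  effects <- list(diagnosis = 2L, age = 3:4, interaction = 5:6)
  for (cv in covariates) {
    X <- cbind(X, scale(as.numeric(ph[[cv]]), scale = FALSE))
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(X = X, effects = effects,
                 df = vapply(effects, length, integer(1)),
                 df_error = nrow(X) - ncol(X),
                 subjects = ph$subject_id, coding = "sum-to-zero"),
            class = "alff_design")
}

#' @export
print.alff_design <- function(x, ...) {
  cat(sprintf("<alff_design> %d subjects x %d columns (%s coding)\n",
              nrow(x$X), ncol(x$X), x$coding))
  cat(sprintf("  effect df: diagnosis %d, age %d, interaction %d; error df %d\n",
              x$df[["diagnosis"]], x$df[["age"]], x$df[["interaction"]],
              x$df_error))
  invisible(x)
}

#' Voxelwise factorial ANCOVA on ALFF maps
#'
#' Fits the full linear model at every in-mask voxel and computes, for each
#' of the diagnosis, age and interaction effects, the partial (Type-III
#' style) F statistic from the reduced model omitting that effect's columns:
#' `F = ((SSE_reduced - SSE_full) / df1) / (SSE_full / df2)`, together with
#' partial eta squared `SS_effect / (SS_effect + SSE_full)` and the
#' one-tailed Z equivalent of the F p-value.
#'
#' @param Y n x V matrix of in-mask map values (one row per subject, subject
#'   order matching the design), e.g. from [alff_matrix()].
#' @param design An [build_design()] result.
#' @param mask Logical 3D mask whose `TRUE` voxels index the columns of `Y`.
#' @return List of three `stat_map` objects (`diagnosis`, `age`,
#'   `interaction`) plus `residuals` (n x V), `sse` and `df_error`.
#' @export
voxelwise_ancova <- function(Y, design, mask) {
  X <- design$X
  if (nrow(Y) != nrow(X)) stop("one map per design row required")
  qf <- qr(X)
  if (qf$rank < ncol(X)) stop("design matrix is rank deficient")
  res_full <- qr.resid(qf, Y)
  sse_full <- colSums(res_full^2)
  df2 <- design$df_error
  # voxels the full model fits exactly (e.g. identical maps across
  # subjects): 0/0 is reported as F = 0, not numerical noise
  degenerate <- sse_full <= 1e-12 * pmax(colSums(Y^2), .Machine$double.xmin)
  maps <- list()
  for (eff in names(design$effects)) {
    cols <- design$effects[[eff]]
    qr_red <- qr(X[, -cols, drop = FALSE])
    sse_red <- colSums(qr.resid(qr_red, Y)^2)
    df1 <- length(cols)
    ss_eff <- pmax(sse_red - sse_full, 0)
    F <- ifelse(degenerate, 0, (ss_eff / df1) / (sse_full / df2))
    eta2 <- ifelse(degenerate, 0, ss_eff / (ss_eff + sse_full))
    maps[[eff]] <- stat_map(F = F, df1 = df1, df2 = df2,
                            partial_eta2 = eta2, effect = eff, mask = mask)
  }
  maps$residuals <- res_full
  maps$sse <- sse_full
  maps$df_error <- df2
  maps
}

#' Voxelwise statistic map
#'
#' @param F Vector of F values over in-mask voxels (or 3D array).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @param partial_eta2 Effect sizes, same layout as `F`.
#' @param effect Label: "diagnosis", "age" or "interaction".
#' @param mask Logical 3D mask.
#' @return Object of class `stat_map` with 3D `F`, `Z` and `partial_eta2`.
#' @export
stat_map <- function(F, df1, df2, partial_eta2, effect, mask) {
  if (is.null(dim(F))) F <- embed_map(F, mask)
  if (is.null(dim(partial_eta2))) partial_eta2 <- embed_map(partial_eta2, mask)
  Z <- array(0, dim(F))
  Z[as.logical(mask)] <- f_to_z(F[as.logical(mask)], df1, df2)
  structure(list(F = F, Z = Z, partial_eta2 = partial_eta2,
                 df1 = df1, df2 = df2, effect = effect, mask = mask),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  inm <- as.logical(x$mask)
  cat(sprintf("<stat_map> %s effect, F(%d, %d), peak F %.2f (Z %.2f), peak partial eta^2 %.3f\n",
              x$effect, x$df1, x$df2, max(x$F[inm]), max(x$Z[inm]),
              max(x$partial_eta2[inm])))
  invisible(x)
}

#' Convert F statistics to one-tailed Z equivalents
#'
#' Z is the standard-normal upper-tail quantile of the upper-tail F
#' probability; the tail is computed on the log scale so very large F values
#' do not underflow.
#'
#' @param F Nonnegative F values.
#' @param df1,df2 Degrees of freedom.
#' @return Z values (same length as `F`).
#' @export
f_to_z <- function(F, df1, df2) {
  logp <- stats::pf(F, df1, df2, lower.tail = FALSE, log.p = TRUE)
  stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
}

#' Post-hoc two-sample t-tests on ROI means
#'
#' Standard (pooled-variance) two-sample t-tests comparing ASD and TC ROI
#' values within each age cohort and pooled over cohorts, with Bonferroni
#' control over the three cohort comparisons (per-comparison alpha
#' `0.05 / 3 = 0.017` to the printed precision).
#'
#' @param roi_values Numeric vector, one ROI mean per subject.
#' @param phenotypes Matching phenotype table.
#' @param family_alpha Familywise alpha (default 0.05) over `n_comparisons`.
#' @param n_comparisons Bonferroni family size (default 3 cohorts).
#' @return `data.frame` with one row per cohort plus a pooled row: t, df, p,
#'   the per-comparison alpha and significance flag.
#' @export
posthoc_ttests <- function(roi_values, phenotypes, family_alpha = 0.05,
                           n_comparisons = 3) {
  alpha <- family_alpha / n_comparisons
  one <- function(sel, label) {
    a <- roi_values[sel & phenotypes$diagnosis == "ASD"]
    b <- roi_values[sel & phenotypes$diagnosis == "TC"]
    if (length(a) < 2 || length(b) < 2)
      stop("need at least 2 subjects per group in ", label)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(comparison = label, n_asd = length(a), n_tc = length(b),
               mean_asd = mean(a), mean_tc = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, alpha = alpha,
               significant = tt$p.value < alpha,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(levels(phenotypes$cohort), function(ch)
    one(phenotypes$cohort == ch, ch))
  pooled <- one(rep(TRUE, length(roi_values)), "pooled")
  pooled$alpha <- family_alpha
  pooled$significant <- pooled$p < family_alpha
  out <- rbind(do.call(rbind, rows), pooled)
  rownames(out) <- NULL
  out
}

#' Stack standardized ALFF maps into a subjects-by-voxels matrix
#'
#' @param maps List of `alff_map` objects sharing a mask.
#' @param mask Logical 3D mask (defaults to the first map's mask).
#' @return n x V matrix of in-mask values.
#' @export
alff_matrix <- function(maps, mask = maps[[1]]$mask) {
  inm <- as.logical(mask)
  t(vapply(maps, function(m) m$values[inm], numeric(sum(inm))))
}
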