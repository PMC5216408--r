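#' Build the voxelwise feature matrix for symptom prediction
#'
#' One row per ASD subject with a non-missing target score; columns are the
#' standardized ALFF values at the voxels of the supplied clusters, ordered
#' by (cluster id, column-major voxel index) so the column order is
#' deterministic across runs. Column provenance (cluster id and 1-based
#' voxel coordinate) is attached.
#'
#' @param Y n x V matrix of in-mask standardized ALFF (all subjects), as
#'   from [alff_matrix()].
#' @param mask Logical 3D mask indexing the columns of `Y`.
#' @param clusters A [extract_clusters()] `cluster_set`, or a list of
#'   coordinate matrices; voxels are pooled across clusters.
#' @param phenotypes Phenotype table matching the rows of `Y`.
#' @param target One of "ados_comm", "ados_social", "ados_stereo".
#' @return List: `X` (subjects x voxels), `y` (observed scores),
#'   `subjects`, `provenance` (data.frame), `n_dropped` (ASD subjects
#'   without a score, excluded).
#' @export
build_feature_matrix <- function(Y, mask, clusters, phenotypes,
                                 target = "ados_social") {
  voxsets <- if (inherits(clusters, "cluster_set")) clusters$voxels else clusters
  if (!length(voxsets)) stop("no clusters to build features from")
  gd <- dim(mask)
  inmask_lin <- which(as.logical(mask))
  prov <- list()
  for (ci in seq_along(voxsets)) {
    co <- voxsets[[ci]]
    lin <- co[, 1] + (co[, 2] - 1) * gd[1] + (co[, 3] - 1) * gd[1] * gd[2]
    ord <- order(lin)
    prov[[ci]] <- data.frame(cluster = ci, linear = lin[ord],
                             x = co[ord, 1], y = co[ord, 2], z = co[ord, 3])
  }
  prov <- do.call(rbind, prov)
  col_idx <- match(prov$linear, inmask_lin)
  if (anyNA(col_idx)) stop("cluster voxels outside the analysis mask")
  asd <- which(phenotypes$diagnosis == "ASD")
  scores <- phenotypes[[target]][asd]
  keep <- !is.na(scores)
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(n_dropped, " ASD subject(s) without ", target, " excluded")
  X <- Y[asd[keep], col_idx, drop = FALSE]
  rownames(X) <- phenotypes$subject_id[asd[keep]]
  list(X = X, y = scores[keep], subjects = phenotypes$subject_id[asd[keep]],
       provenance = prov[, c("cluster", "x", "y", "z")],
       n_dropped = n_dropped, target = target)
}

#' Leave-one-out cross-validated linear SVR predictions
#'
#' For each subject the model is trained on the remaining n - 1 rows and
#' predicts the held-out row. Features are z-scored per column using
#' training-fold statistics only (`scaling = "fold"`, the leakage-free
#' default); `"global"` scaling (all-subject statistics, for demonstrating
#' the leakage effect) and `"none"` are available. The regression is
#' epsilon-insensitive linear SVR ([svr_linear()]).
#'
#' @param X n x p feature matrix.
#' @param y Length-n numeric target.
#' @param C Margin cost (default 1).
#' @param epsilon Insensitivity width (default 0.1).
#' @param scaling "fold", "global" or "none".
#' @param tol Solver stopping tolerance (see [svr_linear()]).
#' @return Length-n vector of out-of-fold predictions.
#' @export
loocv_svr <- function(X, y, C = 1, epsilon = 0.1,
                      scaling = c("fold", "global", "none"), tol = 1e-3) {
  scaling <- match.arg(scaling)
  if (stats::sd(y) == 0)
    warning("constant target: downstream correlation is undefined")
  folds <- prepare_loocv_folds(X, scaling)
  loocv_svr_folds(folds, y, C, epsilon, tol)
}

# Fold-wise scaled training/test matrices. Scaling statistics depend only
# on the features, so the folds can be prepared once and reused across
# permutations of the target without changing any result. When p > n the
# fold's rows are re-expressed in an orthonormal basis of their own row
# space (thin QR): this preserves all inner products, hence the linear-SVR
# solution and predictions, while capping the working dimension at n.
prepare_loocv_folds <- function(X, scaling) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out needs at least 3 subjects")
  if (scaling == "global") {
    mu <- colMeans(X)
    sg <- pmax(apply(X, 2, stats::sd), .Machine$double.eps)
    X <- scale(X, mu, sg)
  }
  lapply(seq_len(n), function(i) {
    Xtr <- X[-i, , drop = FALSE]
    Xte <- X[i, , drop = FALSE]
    if (scaling == "fold") {
      mu <- colMeans(Xtr)
      sg <- pmax(apply(Xtr, 2, stats::sd), .Machine$double.eps)
      Xtr <- scale(Xtr, mu, sg)
      Xte <- scale(Xte, mu, sg)
    }
    if (ncol(Xtr) > n) {
      M <- rbind(Xtr, Xte)
      qq <- qr(t(M))                 # t(M)[, pivot] = Q R
      coords <- matrix(0, n, n)
      coords[qq$pivot, ] <- t(qr.R(qq))  # M = coords %*% t(Q): Gram preserved
      Xtr <- coords[-n, , drop = FALSE]
      Xte <- coords[n, , drop = FALSE]
    }
    list(train = Xtr, test = Xte)
  })
}

loocv_svr_folds <- function(folds, y, C, epsilon, tol = 1e-3) {
  n <- length(folds)
  preds <- numeric(n)
  beta_full <- numeric(n)   # warm start: folds share all but one sample
  for (i in seq_len(n)) {
    # the target is centered with training-fold statistics (leakage-free);
    # the regularized bias then only models residual offset
    mu <- mean(y[-i])
    fit <- svr_linear(folds[[i]]$train, y[-i] - mu, C = C, epsilon = epsilon,
                      tol = tol, beta_init = beta_full[-i])
    beta_full[-i] <- fit$beta
    preds[i] <- predict(fit, folds[[i]]$test) + mu
  }
  preds
}

#' Permutation test for the LOOCV prediction correlation
#'
#' The observed statistic is the Pearson correlation R between the LOOCV
#' predictions and the observed scores. For each permutation the target is
#' shuffled and the FULL leave-one-out procedure (including fold-wise
#' rescaling) is rerun; the p-value is the proportion of permutations with
#' `R_perm > R` (strict inequality). Setting `add_one = TRUE` uses the
#' `(b + 1) / (n_perm + 1)` variant instead.
#'
#' @param X,y,C,epsilon,scaling,tol As in [loocv_svr()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (shuffles are deterministic given it).
#' @param add_one Use the +1-corrected p estimate (default FALSE).
#' @param target Label carried in the result.
#' @return Object of class `prediction_result`: `predicted`, `observed`,
#'   `r`, `permutation_r` (length `n_perm`), `p_perm`, `n`, `target`.
#' @export
permutation_test <- function(X, y, n_perm = 1000, seed = 1, C = 1,
                             epsilon = 0.1, scaling = "fold",
                             add_one = FALSE, target = "", tol = 1e-3) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  folds <- prepare_loocv_folds(X, scaling)
  preds <- loocv_svr_folds(folds, y, C, epsilon, tol)
  r_obs <- stats::cor(preds, y)
  perm_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- sample(y)
      stats::cor(loocv_svr_folds(folds, yp, C, epsilon, tol), yp)
    }, numeric(1))
  })
  p <- if (add_one) (sum(perm_r > r_obs) + 1) / (n_perm + 1)
  else sum(perm_r > r_obs) / n_perm
  structure(list(target = target, predicted = preds, observed = y,
                 r = r_obs, permutation_r = perm_r, p_perm = p,
                 n = length(y), n_perm = n_perm,
                 bonferroni_alpha = 0.05 / 3),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result>%s n = %d: R = %.3f, permutation p = %.4g (%d permutations)\n",
              if (nzchar(x$target)) paste0(" [", x$target, "]") else "",
              x$n, x$r, x$p_perm, x$n_perm))
  invisible(x)
}

#' Bonferroni gate over the three ADOS subscale tests
#'
#' Significance requires `p < family_alpha / 3` (strict inequality; a
#' p-value exactly at the threshold is not significant).
#'
#' @param p_values Named or unnamed numeric vector of exactly 3 p-values.
#' @param family_alpha Familywise alpha (default 0.05).
#' @return Logical vector of significance flags with attribute `alpha`.
#' @export
bonferroni_gate <- function(p_values, family_alpha = 0.05) {
  if (length(p_values) != 3) stop("expected exactly 3 subscale p-values")
  alpha <- family_alpha / 3
  structure(p_values < alpha, alpha = alpha)
}
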