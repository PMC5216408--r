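#' Linear epsilon-insensitive support-vector regression
#'
#' L2-regularized L1-loss (epsilon-insensitive) linear SVR,
#' `min_w 0.5 ||w||^2 + C sum_i max(0, |w'x_i - y_i| - epsilon)`,
#' solved by dual coordinate descent in the LIBLINEAR style. The intercept
#' is a regularized bias term (every sample is augmented with a constant
#' bias feature of value 1).
#'
#' @param X n x p numeric feature matrix.
#' @param y Length-n numeric target.
#' @param C Margin cost (default 1).
#' @param epsilon Insensitivity width (default 0.1).
#' @param bias Bias-feature value (default 1; 0 fits without intercept).
#' @param tol Stopping tolerance: the sweep stops when the summed
#'   projected-gradient violation falls below `tol` times its initial value
#'   (default 1e-4).
#' @param max_passes Maximum coordinate sweeps (default 5000).
#' @param beta_init Optional warm-start dual coefficients (clipped into
#'   the feasible box); the solution is unchanged, only convergence speed.
#' @return Object of class `linear_svr`: `w`, `intercept`, `beta` (dual
#'   coefficients), `passes`, `converged`.
#' @export
svr_linear <- function(X, y, C = 1, epsilon = 0.1, bias = 1,
                       tol = 1e-4, max_passes = 5000, beta_init = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  fit <- .svr_cd_fit(X, as.double(y), C, epsilon, bias, tol,
                     as.integer(max_passes), beta_init)
  if (!fit$converged)
    warning("SVR coordinate descent did not converge in ", max_passes,
            " passes")
  structure(fit, class = "linear_svr")
}

#' @export
predict.linear_svr <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$w) + object$intercept
}

#' @export
print.linear_svr <- function(x, ...) {
  cat(sprintf("<linear_svr> %d features, intercept %.4g, %d support vector(s), %d passes\n",
              length(x$w), x$intercept, sum(abs(x$beta) > 1e-12), x$passes))
  invisible(x)
}
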