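#' Quadratic age-trajectory fit for ROI ALFF
#'
#' Least-squares fit of `alff ~ 1 + age + age^2` within one diagnosis group.
#' Ages are mean-centered before the quadratic term is formed (collinearity
#' control); reported coefficients are transformed back to the raw-age
#' basis. Model significance is the overall F test against the
#' intercept-only model, `F = (R^2 / 2) / ((1 - R^2) / (n - 3))` with
#' (2, n - 3) degrees of freedom.
#'
#' @param ages Numeric ages in years.
#' @param alff_values Numeric ROI ALFF values (same length).
#' @param group Group label carried in the result (default "").
#' @return Object of class `quad_fit`: raw-basis `coefficients`
#'   (b0, b1 per year, b2 per year^2), centered-basis `coefficients_centered`,
#'   `age_center`, `r_squared`, `f_statistic`, `df`, `p_value`, `n`,
#'   `fitted`, `residuals`.
#' @export
fit_quadratic <- function(ages, alff_values, group = "") {
  n <- length(ages)
  if (n < 4) stop("quadratic fit needs at least 4 observations")
  if (length(alff_values) != n) stop("ages and values differ in length")
  if (stats::sd(ages) == 0) stop("degenerate ages: all equal")
  m <- mean(ages)
  a <- ages - m
  X <- cbind(1, a, a^2)
  if (qr(X)$rank < 3) stop("collinear age design (too few distinct ages)")
  fit <- stats::lm.fit(X, alff_values)
  b <- fit$coefficients
  fitted <- drop(X %*% b)
  sse <- sum((alff_values - fitted)^2)
  sst <- sum((alff_values - mean(alff_values))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  df <- c(2, n - 3)
  F <- (r2 / df[1]) / ((1 - r2) / df[2])
  p <- stats::pf(F, df[1], df[2], lower.tail = FALSE)
  raw <- c(b0 = b[1] - b[2] * m + b[3] * m^2,
           b1 = b[2] - 2 * b[3] * m,
           b2 = b[3])
  names(raw) <- c("b0", "b1", "b2")
  structure(list(group = group, coefficients = raw,
                 coefficients_centered = stats::setNames(b, c("c0", "c1", "c2")),
                 age_center = m, r_squared = r2, f_statistic = F, df = df,
                 p_value = p, n = n, ages = ages, observed = alff_values,
                 fitted = fitted, residuals = alff_values - fitted),
            class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("<quad_fit>%s n = %d\n",
              if (nzchar(x$group)) paste0(" [", x$group, "]") else "", x$n))
  cat(sprintf("  alff = %.4g %+.4g age %+.4g age^2\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  R^2 = %.3f, F(%d, %d) = %.3f, p = %.4g\n",
              x$r_squared, x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' @export
predict.quad_fit <- function(object, newages, ...) {
  b <- object$coefficients
  b[1] + b[2] * newages + b[3] * newages^2
}

#' @export
coef.quad_fit <- function(object, ...) object$coefficients

#' @export
residuals.quad_fit <- function(object, ...) object$residuals

#' Side-by-side comparison of two group trajectories
#'
#' @param fit_tc,fit_asd [fit_quadratic()] results for the two groups on the
#'   same ROI.
#' @param n_grid Number of ages at which the fitted curves are sampled over
#'   the pooled age range (default 50).
#' @return Object of class `trajectory_report`: `table` (one row per group:
#'   coefficients, R^2, F, p, n) and `curves` (long data.frame of fitted
#'   values over the pooled age grid).
#' @export
compare_group_trajectories <- function(fit_tc, fit_asd, n_grid = 50) {
  row <- function(f) data.frame(
    group = f$group, n = f$n, b0 = f$coefficients[1], b1 = f$coefficients[2],
    b2 = f$coefficients[3], r_squared = f$r_squared, f = f$f_statistic,
    df1 = f$df[1], df2 = f$df[2], p = f$p_value, row.names = NULL)
  ages <- seq(min(fit_tc$ages, fit_asd$ages),
              max(fit_tc$ages, fit_asd$ages), length.out = n_grid)
  curves <- rbind(
    data.frame(group = fit_tc$group, age = ages,
               fitted = predict(fit_tc, ages)),
    data.frame(group = fit_asd$group, age = ages,
               fitted = predict(fit_asd, ages)))
  structure(list(table = rbind(row(fit_tc), row(fit_asd)), curves = curves),
            class = "trajectory_report")
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat("<trajectory_report>\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Scatter and fitted-curve plot of two group trajectories (diagnostic)
#'
#' @param x A `trajectory_report`.
#' @param ... Passed to [plot()].
#' @export
plot.trajectory_report <- function(x, ...) {
  groups <- unique(x$curves$group)
  cols <- stats::setNames(c("#1b6ca8", "#c0392b")[seq_along(groups)], groups)
  plot(x$curves$age, x$curves$fitted, type = "n",
       xlab = "age (years)", ylab = "ROI ALFF", ...)
  for (g in groups) {
    cv <- x$curves[x$curves$group == g, ]
    graphics::lines(cv$age, cv$fitted, col = cols[[g]], lwd = 2)
  }
  graphics::legend("topright", legend = groups, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
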