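# Shared fixtures: a desk-scale simulation config and independent oracles.

# Small grid / short run for fast unit tests (full default config is
# exercised in the acceptance tests).
tiny_config <- function(n_volumes = 80, freq_grid_n = n_volumes - 10, ...) {
  simulation_config(
    grid_dims = c(14, 16, 14), n_volumes = n_volumes,
    freq_grid_n = freq_grid_n,
    regions = list(
      mPFC = region_effect("mPFC", center = c(8, 13, 9), radius = 1.8,
                           coef = list(TC = c(1.2, 0, 0), ASD = c(0.7, 0, 0))),
      precuneus = region_effect("precuneus", center = c(8, 4, 9), radius = 1.5,
                                coef = list(TC = c(1.0, 0, 0), ASD = c(0.7, 0, 0)))),
    symptom_coupling = list(weights = c(mPFC = 6, precuneus = 6),
                            intercept = -4, noise_sd = 2, range = c(0, 14)),
    ...)
}

tiny_cohort <- function(n = 3) {
  cohort_spec(cell_sizes = list(child = c(ASD = n, TC = n),
                                adolescent = c(ASD = n, TC = n),
                                adult = c(ASD = n, TC = n)))
}

# Brute-force O(N^2) DFT ALFF oracle, written independently of the package's
# FFT path: explicit complex exponential sums, one-sided power with
# Parseval-preserving doubling, mean sqrt(power) over band bins.
brute_force_alff <- function(ts, tr, band = c(0.01, 0.08)) {
  N <- length(ts)
  m <- floor(N / 2)
  vals <- numeric(0)
  for (k in 0:m) {
    re <- sum(ts * cos(-2 * pi * k * (0:(N - 1)) / N))
    im <- sum(ts * sin(-2 * pi * k * (0:(N - 1)) / N))
    pw <- (re^2 + im^2) / N
    if (k != 0 && !(N %% 2 == 0 && k == m)) pw <- 2 * pw
    f <- k / (N * tr)
    if (f >= band[1] && f <= band[2]) vals <- c(vals, sqrt(pw))
  }
  mean(vals)
}

# Independent SVR oracle: solves the identical dual QP
#   min 0.5 (a - a*)' K (a - a*) + eps 1'(a + a*) - y'(a - a*)
#   0 <= a, a* <= C,  K = X~ X~' with the bias-augmented features,
# with kernlab's interior-point QP solver, then recovers w and predictions.
qp_svr_oracle <- function(X, y, C = 1, epsilon = 0.1, bias = 1) {
  Xa <- cbind(X, bias)
  n <- nrow(Xa)
  K <- Xa %*% t(Xa)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-8, 2 * n)
  cc <- c(epsilon - y, epsilon + y)
  # the linear constraint is nonbinding (it restates the box bounds); it
  # keeps the interior-point KKT system nonsingular
  sol <- kernlab::ipop(c = cc, H = H,
                       A = matrix(1, 1, 2 * n), b = 0, r = 2 * n * C,
                       l = rep(0, 2 * n), u = rep(C, 2 * n),
                       sigf = 8, maxiter = 300)
  ab <- kernlab::primal(sol)
  beta <- ab[1:n] - ab[(n + 1):(2 * n)]
  w <- unname(drop(t(Xa) %*% beta))
  list(w = w[-length(w)], intercept = w[length(w)] * bias, beta = beta,
       predict = function(newX) drop(cbind(newX, bias) %*% w))
}

# Independent GLM oracle: lm() with sum-to-zero contrasts and Type-III
# (partial) F tests from car::Anova.
lm_ancova_oracle <- function(y, ph) {
  dat <- data.frame(y = y, diagnosis = ph$diagnosis, cohort = ph$cohort,
                    gender = ph$gender - mean(ph$gender),
                    fiq = ph$fiq - mean(ph$fiq),
                    mean_fd = ph$mean_fd - mean(ph$mean_fd))
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  full <- lm(y ~ diagnosis * cohort + gender + fiq + mean_fd, dat)
  an <- car::Anova(full, type = "III")
  sse <- an["Residuals", "Sum Sq"]
  pick <- function(term) {
    list(F = an[term, "F value"], df1 = an[term, "Df"],
         df2 = an["Residuals", "Df"],
         eta2 = an[term, "Sum Sq"] / (an[term, "Sum Sq"] + sse))
  }
  list(diagnosis = pick("diagnosis"), age = pick("cohort"),
       interaction = pick("diagnosis:cohort"))
}
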