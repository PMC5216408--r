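fake_phen <- function(n_per_cell = 2, seed = 1) {
  spec <- tiny_cohort(n_per_cell)
  ph <- generate_phenotypes(spec, seed)
  ph$mean_fd <- runif(nrow(ph), 0.05, 0.2)
  ph
}

test_that("the default design has 9 columns and error df 119", {
  ph <- generate_phenotypes(seed = 1)
  ph$mean_fd <- runif(128, 0.05, 0.2)
  d <- build_design(ph)
  expect_equal(dim(d$X), c(128L, 9L))
  expect_equal(qr(d$X)$rank, 9)
  expect_equal(d$df_error, 119)
  expect_equal(unname(d$df[c("diagnosis", "age", "interaction")]),
               c(1L, 2L, 2L))
  d0 <- build_design(ph, covariates = character(0))
  expect_equal(d0$df_error, 122)  # dropping 3 covariates raises df by 3
})

test_that("balanced effects coding gives orthogonal effect blocks", {
  spec <- tiny_cohort(4)   # fully balanced 2x3
  ph <- generate_phenotypes(spec, 2)
  ph$mean_fd <- runif(nrow(ph))
  d <- build_design(ph, covariates = character(0))
  # in a balanced design the intercept, diagnosis, age and interaction
  # blocks are mutually orthogonal under sum-to-zero coding
  blocks <- list(1L, d$effects$diagnosis, d$effects$age, d$effects$interaction)
  for (a in 1:3) for (b in (a + 1):4) {
    G <- crossprod(d$X[, blocks[[a]], drop = FALSE],
                   d$X[, blocks[[b]], drop = FALSE])
    expect_equal(max(abs(G)), 0, tolerance = 1e-12)
  }
  ph_miss <- ph[ph$cohort != "adult", ]
  expect_error(build_design(ph_miss, covariates = character(0)), "cohorts")
})

test_that("voxelwise ANCOVA matches the lm/car Type-III oracle to 1e-8", {
  set.seed(31)
  ph <- fake_phen(2)   # 12-subject toy design
  mask <- array(TRUE, c(3, 2, 1))
  Y <- matrix(rnorm(12 * 6), 12, 6)
  d <- build_design(ph)
  res <- voxelwise_ancova(Y, d, mask)
  for (v in 1:6) {
    oracle <- lm_ancova_oracle(Y[, v], ph)
    for (eff in c("diagnosis", "age", "interaction")) {
      expect_equal(res[[eff]]$F[v], oracle[[eff]]$F, tolerance = 1e-8)
      expect_equal(res[[eff]]$partial_eta2[v], oracle[[eff]]$eta2,
                   tolerance = 1e-8)
      expect_equal(res[[eff]]$df1, oracle[[eff]]$df1)
      expect_equal(res[[eff]]$df2, oracle[[eff]]$df2)
    }
  }
})

test_that("identical maps across subjects give F = 0 and eta2 identities hold", {
  set.seed(32)
  ph <- fake_phen(3)
  mask <- array(TRUE, c(2, 2, 2))
  Y0 <- matrix(rep(rnorm(8), each = nrow(ph)), nrow(ph), 8)
  d <- build_design(ph)
  res0 <- voxelwise_ancova(Y0, d, mask)
  expect_true(all(res0$diagnosis$F == 0))
  expect_true(all(res0$interaction$F == 0))
  Y <- Y0 + matrix(rnorm(nrow(ph) * 8), nrow(ph), 8)
  res <- voxelwise_ancova(Y, d, mask)
  for (eff in c("diagnosis", "age", "interaction")) {
    sm <- res[[eff]]
    # partial eta^2 = F df1 / (F df1 + df2) at every voxel
    expect_equal(sm$partial_eta2[mask],
                 (sm$F[mask] * sm$df1) / (sm$F[mask] * sm$df1 + sm$df2),
                 tolerance = 1e-10)
  }
})

test_that("partial and sequential sums of squares coincide in balanced designs", {
  set.seed(33)
  spec <- tiny_cohort(4)
  ph <- generate_phenotypes(spec, 3)
  y <- rnorm(nrow(ph))
  d <- build_design(ph, covariates = character(0))
  mask <- array(TRUE, c(1, 1, 1))
  res <- voxelwise_ancova(matrix(y), d, mask)
  seq_aov <- anova(lm(y ~ diagnosis * cohort, ph,
                      contrasts = list(diagnosis = "contr.sum",
                                       cohort = "contr.sum")))
  expect_equal(res$diagnosis$F[1], seq_aov["diagnosis", "F value"],
               tolerance = 1e-10)
  expect_equal(res$age$F[1], seq_aov["cohort", "F value"], tolerance = 1e-10)
  expect_equal(res$interaction$F[1], seq_aov["diagnosis:cohort", "F value"],
               tolerance = 1e-10)
})

test_that("F-to-Z conversion reproduces the quoted threshold pairing", {
  # p = 0.01 corresponds to Z ~ 2.33 (2.326 to 3 dp)
  F01 <- qf(0.01, 1, 119, lower.tail = FALSE)
  expect_equal(f_to_z(F01, 1, 119), qnorm(0.99), tolerance = 1e-10)
  expect_equal(round(qnorm(0.99), 2), 2.33)
  # F at the distribution median maps to Z ~ 0
  expect_equal(f_to_z(qf(0.5, 2, 119), 2, 119), 0, tolerance = 1e-10)
  # monotone increasing, and no underflow at extreme F
  Fs <- c(0.1, 1, 5, 20, 100, 1000)
  zs <- f_to_z(Fs, 2, 119)
  expect_true(all(diff(zs) > 0))
  expect_true(all(is.finite(zs)))
})

test_that("post-hoc t-tests use the 0.05/3 Bonferroni threshold", {
  set.seed(34)
  ph <- fake_phen(6)
  roi <- rnorm(nrow(ph))
  tab <- posthoc_ttests(roi, ph)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$alpha[1], 0.05 / 3)
  expect_equal(round(tab$alpha[1], 3), 0.017)
  # identical groups (same values in ASD and TC): t = 0, p = 1
  roi_sym <- numeric(nrow(ph))
  for (ch in levels(ph$cohort)) {
    vals <- rnorm(6)
    roi_sym[ph$cohort == ch & ph$diagnosis == "ASD"] <- vals
    roi_sym[ph$cohort == ch & ph$diagnosis == "TC"] <- vals
  }
  tab2 <- posthoc_ttests(roi_sym, ph)
  expect_equal(tab2$t, rep(0, 4), tolerance = 1e-12)
  expect_equal(tab2$p, rep(1, 4), tolerance = 1e-12)
  # pooled two-group t^2 equals the one-way ANOVA F
  pooled <- tab[tab$comparison == "pooled", ]
  Fv <- anova(lm(roi ~ ph$diagnosis))["ph$diagnosis", "F value"]
  expect_equal(pooled$t^2, Fv, tolerance = 1e-10)
})
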