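test_that("feature matrices pool cluster voxels in deterministic order", {
  gd <- c(8, 8, 8)
  mask <- array(TRUE, gd)
  set.seed(61)
  ph <- generate_phenotypes(tiny_cohort(2), 1)
  ph$ados_social[ph$diagnosis == "ASD"] <- rpois(6, 7)
  Y <- matrix(rnorm(nrow(ph) * prod(gd)), nrow(ph), prod(gd))
  clusters <- list(as.matrix(expand.grid(1:4, 1:5, 1)),      # 20 voxels
                   as.matrix(expand.grid(6:7, 6:7, 2:3)),    # 8 voxels
                   cbind(8, 8, 5:8))                         # 4 voxels
  fm <- build_feature_matrix(Y, mask, clusters, ph, "ados_social")
  expect_equal(ncol(fm$X), 20 + 8 + 4)
  expect_equal(nrow(fm$X), 6)
  expect_equal(fm$provenance$cluster, rep(1:3, c(20, 8, 4)))
  fm2 <- build_feature_matrix(Y, mask, clusters, ph, "ados_social")
  expect_identical(fm$X, fm2$X)
  # subjects without a score are dropped with a message
  ph2 <- ph; ph2$ados_social[which(ph2$diagnosis == "ASD")[1]] <- NA
  expect_message(
    fm3 <- build_feature_matrix(Y, mask, clusters, ph2, "ados_social"),
    "excluded")
  expect_equal(nrow(fm3$X), 5)
  # single-subject edge case
  ph1 <- ph[ph$diagnosis == "ASD", ][1, ]
  fm1 <- build_feature_matrix(Y[1, , drop = FALSE], mask, clusters, ph1,
                              "ados_social")
  expect_equal(dim(fm1$X), c(1L, 32L))
})

test_that("LOOCV recovers a noiseless linear signal and not pure noise", {
  set.seed(62)
  n <- 30; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- 3 + 2 * X[, 1]
  pr <- loocv_svr(X, y)
  expect_gt(cor(pr, y), 0.99)
  ynull <- rnorm(n)
  rs <- replicate(20, {
    yn <- sample(ynull)
    cor(loocv_svr(X, yn), yn)
  })
  expect_lt(abs(mean(rs)), 0.25)
})

test_that("the solver matches the QP oracle on a 6-sample worked fixture", {
  skip_if_not_installed("kernlab")
  set.seed(63)
  X <- matrix(c(0.5, -1.2, 0.3,
                1.1, 0.4, -0.7,
                -0.9, 0.8, 1.5,
                0.2, -0.5, -1.1,
                1.4, 1.0, 0.6,
                -0.3, -1.4, 0.9), 6, 3, byrow = TRUE)
  y <- c(1.2, 0.4, -0.8, 0.1, 2.0, -1.5)
  for (C in c(0.5, 1, 5)) {
    fit <- svr_linear(X, y, C = C, epsilon = 0.1, tol = 1e-10)
    oracle <- qp_svr_oracle(X, y, C = C, epsilon = 0.1)
    expect_equal(fit$w, oracle$w, tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-4)
    Xnew <- matrix(rnorm(9), 3, 3)
    expect_equal(predict(fit, Xnew), oracle$predict(Xnew), tolerance = 1e-4)
  }
})

test_that("fold-wise scaling differs from leaky global scaling", {
  set.seed(64)
  n <- 12; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  # an extreme held-out subject inflates global column statistics
  X[1, ] <- X[1, ] + 25
  y <- X[, 2] + rnorm(n, 0, 0.1)
  pr_fold <- loocv_svr(X, y, scaling = "fold")
  pr_global <- loocv_svr(X, y, scaling = "global")
  expect_gt(max(abs(pr_fold - pr_global)), 1e-3)
})

test_that("the permutation test is deterministic, strict and order-invariant", {
  set.seed(65)
  n <- 16; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- 2 * X[, 1] + rnorm(n, 0, 0.3)
  r1 <- permutation_test(X, y, n_perm = 50, seed = 9)
  r2 <- permutation_test(X, y, n_perm = 50, seed = 9)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_identical(r1$permutation_r, r2$permutation_r)
  expect_equal(r1$p_perm, mean(r1$permutation_r > r1$r))
  # relabeling subject order leaves p unchanged (same seed, permuted rows)
  # (the permutation distribution is over relabelings, so any fixed row
  # order yields the same observed R)
  ord <- sample(n)
  r3 <- permutation_test(X[ord, ], y[ord], n_perm = 50, seed = 9)
  expect_equal(r3$r, r1$r, tolerance = 1e-2)   # solver-tolerance level
  # near-perfect prediction: no permutation exceeds the observed R
  yl <- 5 + 3 * X[, 2]
  rp <- permutation_test(X, yl, n_perm = 50, seed = 10)
  expect_equal(rp$p_perm, 0)
  # +1 variant bounds p away from zero
  rp1 <- permutation_test(X, yl, n_perm = 50, seed = 10, add_one = TRUE)
  expect_equal(rp1$p_perm, 1 / 51)
  expect_error(permutation_test(X, y, n_perm = 0), "at least 1")
})

test_that("the Bonferroni gate uses a strict 0.05/3 cut", {
  flags <- bonferroni_gate(c(comm = 0.2, social = 0.005, stereo = 0.5))
  expect_equal(as.logical(flags), c(FALSE, TRUE, FALSE))
  expect_equal(attr(flags, "alpha"), 0.05 / 3)
  expect_false(as.logical(bonferroni_gate(c(0.017, 0.5, 0.9))[1]))
  expect_error(bonferroni_gate(c(0.01, 0.02)), "exactly 3")
})
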