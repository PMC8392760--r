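test_that("the Matern 5/2 closed form matches the Bessel-function definition", {
  nu <- 2.5; ell <- 0.7; sf2 <- 1.9
  r <- c(0.05, 0.3, 1, 2.7)
  a <- sqrt(2 * nu) * r / ell
  bessel <- sf2 * 2^(1 - nu) / gamma(nu) * a^nu * besselK(a, nu)
  expect_equal(as.numeric(mlifpet:::matern52(matrix(r^2, 1), ell, sf2)),
               bessel, tolerance = 1e-10)
  expect_equal(as.numeric(mlifpet:::matern52(matrix(0, 1), ell, sf2)), sf2)
})

test_that("normalisation constants are per-channel cohort maxima", {
  t <- 0:9
  mk <- function(p) make_idif_set(
    new_tac(t, p * sin(t / 3 + 1)^2, "uniform"),
    new_tac(t, 0.8 * p * sin(t / 3 + 1)^2, "uniform"),
    new_tac(t, 0.5 * p * sin(t / 3 + 1)^2, "uniform"))
  sets <- list(mk(5), mk(8))
  norm <- fit_normalization(sets)
  # each channel max over subjects (subject 2 dominates every channel)
  expect_equal(norm[["peak10"]], max(sets[[2]]$idif10$value))
  expect_equal(norm[["peak100"]], max(sets[[2]]$idif100$value))
  # permutation invariance
  expect_equal(norm, fit_normalization(rev(sets)))
  # single subject: its own peaks
  expect_equal(fit_normalization(sets[1])[["peak10"]],
               max(sets[[1]]$idif10$value))
})

test_that("normalised training inputs lie in [0, 1] and scale linearly", {
  t <- 0:9
  mk <- function(p) make_idif_set(
    new_tac(t, p * (t + 1), "uniform"),
    new_tac(t, p * (t + 1) / 2, "uniform"),
    new_tac(t, p * (t + 1) / 4, "uniform"))
  sets <- list(mk(1), mk(2))
  norm <- fit_normalization(sets)
  for (s in sets) {
    x <- normalize_idifs(s, norm)
    expect_true(all(x >= 0 & x <= 1))
  }
  # cohort-max channel maps to exactly 1
  expect_equal(max(normalize_idifs(sets[[2]], norm)[1:10]), 1)
  # linearity: scaling a test set by c scales its vector by c
  x1 <- normalize_idifs(mk(3), norm)
  x2 <- normalize_idifs(mk(6), norm)
  expect_equal(x2, 2 * x1)
  expect_error(normalize_idifs(sets[[1]], c(peak10 = 0, peak100 = 1,
                                            peak1000 = 1)), "> 0")
})

test_that("training improves the marginal likelihood and is deterministic", {
  toy <- toy_gp_set()
  norm <- c(peak10 = 1, peak100 = 1, peak1000 = 1)
  m1 <- gp_train(toy$X, toy$Y, norm)
  m2 <- gp_train(toy$X, toy$Y, norm)
  expect_identical(m1$ell, m2$ell)
  expect_identical(m1$sn2, m2$sn2)
  expect_lte(m1$nll, m1$nll0)  # optimisation never worsens the objective
  expect_error(gp_train(toy$X[1, , drop = FALSE], toy$Y[1, , drop = FALSE],
                        norm), "at least 2")
})

test_that("GP predictions match a dense-solve oracle to 1e-8 relative", {
  toy <- toy_gp_set()
  m <- gp_train(toy$X, toy$Y, c(peak10 = 1, peak100 = 1, peak1000 = 1))
  set.seed(405)
  xs <- runif(ncol(toy$X))
  p <- gp_predict(m, xs)
  # oracle: brute-force matrix inversion of the predictive equations
  K <- mlifpet:::matern52(mlifpet:::cross_dist2(m$X, m$X), m$ell, m$sf2) +
    (m$sn2 + 1e-10 * m$sf2) * diag(nrow(m$X))
  ks <- mlifpet:::matern52(mlifpet:::cross_dist2(matrix(xs, 1), m$X),
                           m$ell, m$sf2)
  mu_oracle <- as.numeric(ks %*% solve(K) %*% m$Y)
  v_oracle <- m$sf2 - as.numeric(ks %*% solve(K) %*% t(ks))
  expect_equal(p$mean$value, mu_oracle, tolerance = 1e-8)
  expect_equal(p$variance[1], v_oracle, tolerance = 1e-8)
})

test_that("the GP interpolates training subjects as noise vanishes", {
  toy <- toy_gp_set()
  norm <- c(peak10 = 1, peak100 = 1, peak1000 = 1)
  m <- gp_train(toy$X, toy$Y, norm)
  m$sn2 <- 1e-12  # clamp noise and rebuild the factorisation
  K <- mlifpet:::matern52(mlifpet:::cross_dist2(m$X, m$X), m$ell, m$sf2) +
    (m$sn2 + 1e-10 * m$sf2) * diag(nrow(m$X))
  m$L <- chol(K)
  m$alpha <- backsolve(m$L, forwardsolve(t(m$L), m$Y))
  p <- gp_predict(m, m$X[3, ])
  expect_equal(p$mean$value, unname(toy$Y[3, ]), tolerance = 1e-3)
  # variance at a training input is below the far-field variance
  far <- gp_predict(m, m$X[3, ] + 100)
  expect_lt(p$variance[1], far$variance[1])
  expect_gte(p$variance[1], 0)
})

test_that("predictions are invariant to training-subject permutation and jitter", {
  toy <- toy_gp_set()
  norm <- c(peak10 = 1, peak100 = 1, peak1000 = 1)
  m <- gp_train(toy$X, toy$Y, norm)
  perm <- c(3, 1, 5, 2, 4)
  mp <- gp_train(toy$X[perm, ], toy$Y[perm, ], norm)
  set.seed(406)
  xs <- runif(ncol(toy$X))
  expect_equal(gp_predict(m, xs)$mean$value, gp_predict(mp, xs)$mean$value,
               tolerance = 1e-6)
  # jitter robustness: adding <= 1e-6 sf2 to the diagonal barely moves output
  m2 <- m
  K <- mlifpet:::matern52(mlifpet:::cross_dist2(m$X, m$X), m$ell, m$sf2) +
    (m$sn2 + 1e-6 * m$sf2) * diag(nrow(m$X))
  m2$L <- chol(K)
  m2$alpha <- backsolve(m2$L, forwardsolve(t(m2$L), m$Y))
  rel <- max(abs(gp_predict(m2, xs)$mean$value - gp_predict(m, xs)$mean$value)) /
    max(abs(gp_predict(m, xs)$mean$value))
  expect_lt(rel, 1e-3)
})

test_that("hyperparameter optimisation recovers a known lengthscale", {
  set.seed(407)
  N <- 40; d <- 5; T <- 50; ell_true <- 0.8
  X <- matrix(runif(N * d), N, d)
  K <- mlifpet:::matern52(mlifpet:::cross_dist2(X, X), ell_true, 1) +
    1e-8 * diag(N)
  L <- chol(K)
  Y <- t(L) %*% matrix(rnorm(N * T), N, T)
  m <- gp_train(X, Y, c(peak10 = 1, peak100 = 1, peak1000 = 1),
                init = list(ell = 0.3, sf2 = 0.5, sn2 = 1e-4))
  expect_lt(abs(m$ell - ell_true) / ell_true, 0.25)
})

test_that("leave-one-out returns one honest prediction per scan", {
  t <- 0:19
  set.seed(408)
  mk_scan <- function(p) {
    shape <- p * exp(-(t - 6)^2 / 18)
    list(idifs = make_idif_set(
      new_tac(t, shape, "uniform"),
      new_tac(t, 0.7 * shape, "uniform"),
      new_tac(t, 0.4 * shape, "uniform")),
      aif = new_tac(t, 1.6 * p * exp(-(t - 5)^2 / 20), "uniform"))
  }
  cohort <- lapply(runif(5, 1, 3), mk_scan)
  preds <- gp_loo(cohort)
  expect_length(preds, 5L)
  expect_error(gp_loo(cohort[1:2]), ">= 3")
  # duplicating a subject puts its twin in training: held-out error collapses
  err <- function(preds, cohort, i)
    sqrt(mean((preds[[i]]$mean$value - cohort[[i]]$aif$value)^2))
  base_err <- err(preds, cohort, 1)
  cohort2 <- c(cohort, cohort[1])
  preds2 <- gp_loo(cohort2)
  expect_lt(err(preds2, cohort2, 1), base_err)
})

test_that("predicting a mean-shaped input does not overshoot the training peaks", {
  fx <- small_cohort()
  recs <- fx$records$baseline
  model <- gp_train_cohort(recs)
  Xbar <- colMeans(model$X)
  p <- gp_predict(model, Xbar)
  max_train_peak <- max(model$Y)
  expect_lt(max(p$mean$value), 1.25 * max_train_peak)
})
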