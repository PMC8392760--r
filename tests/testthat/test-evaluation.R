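test_that("orthogonal regression handles exact lines", {
  x <- c(1, 2, 3, 4, 5)
  r <- orthogonal_regression(x, x)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$r2, 1)
  r2 <- orthogonal_regression(x, 2 * x + 1)
  expect_equal(r2$slope, 2, tolerance = 1e-12)
  expect_equal(r2$intercept, 1, tolerance = 1e-12)
  expect_error(orthogonal_regression(x, x[1:3]), "lengths differ")
  expect_error(orthogonal_regression(rep(2, 5), rep(3, 5)), "degenerate")
})

test_that("TLS slope matches the SVD oracle and swap symmetry", {
  set.seed(31)
  for (rep in 1:10) {
    x <- rnorm(30); y <- 1.4 * x + rnorm(30, sd = 0.5)
    r <- orthogonal_regression(x, y)
    # oracle: smallest-singular-vector of the centred data matrix
    M <- cbind(x - mean(x), y - mean(y))
    v <- svd(M)$v[, 2]
    expect_equal(r$slope, -v[1] / v[2], tolerance = 1e-10)
    # slope(x,y) * slope of the swapped fit = 1
    expect_equal(r$slope * orthogonal_regression(y, x)$slope, 1,
                 tolerance = 1e-10)
  }
})

test_that("the scaled-MAD rule flags only the aberrant slope", {
  s <- c(0.8, 0.85, 0.9, 0.87, 2.5)
  flags <- flag_slope_outliers(s)
  expect_equal(flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # recomputed threshold: median 0.87, MAD 0.03, scaled 0.044478
  med <- 0.87; thr <- 3 * 1.4826 * 0.03
  expect_equal(flags, abs(s - med) > thr)
  # equal slopes: nothing flagged
  expect_false(any(flag_slope_outliers(rep(0.9, 5))))
  # MAD = 0 with one deviant: limit of the rule flags it
  expect_equal(flag_slope_outliers(c(1, 1, 1, 1.2)),
               c(FALSE, FALSE, FALSE, TRUE))
  # translation invariance
  expect_equal(flag_slope_outliers(s + 10), flags)
  # idempotence after removal: no new point crosses the threshold
  expect_false(any(flag_slope_outliers(s[!flags])))
})

test_that("Bland-Altman limits match the direct mean/SD computation", {
  a <- c(1, 2, 3, 4)
  ba <- bland_altman(a, a)
  expect_equal(unlist(ba), c(bias = 0, loa_low = 0, loa_high = 0))
  ba1 <- bland_altman(a + 1, a)
  expect_equal(unlist(ba1), c(bias = 1, loa_low = 1, loa_high = 1))
  set.seed(32)
  x <- rnorm(25); y <- rnorm(25)
  ba2 <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba2$bias, mean(d))
  expect_equal(ba2$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba2$loa_high, mean(d) + 1.96 * sd(d))
  expect_true(ba2$loa_low <= ba2$bias && ba2$bias <= ba2$loa_high)
})

test_that("paired comparison reproduces the closed-form t statistic", {
  a <- c(5, 7, 6, 9, 8)
  pc <- paired_comparison(a, a)
  expect_equal(pc$t_stat, 0)
  expect_equal(pc$p_value, 1)
  expect_equal(pc$mean_ratio, 1)
  b <- c(4.8, 7.5, 5.5, 9.4, 7.7)
  pc2 <- paired_comparison(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(pc2$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(pc2$p_value, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  expect_equal(pc2$mean_ratio, mean(a / b))
  expect_error(paired_comparison(a, c(0, 1, 2, 3, 4)), "zero denominator")
})

test_that("case 3 with identical local and arterial inputs matches the AIF change", {
  # noiseless toy records in which idif10 IS the arterial curve
  t <- 0:360
  mk_rec <- function(cbf) {
    aif <- smooth_bolus(t)
    list(idifs = make_idif_set(aif,
                               new_tac(t, 0.7 * aif$value, "uniform"),
                               new_tac(t, 0.4 * aif$value, "uniform")),
         aif = aif,
         tissue = simulate_tissue(aif, cbf, cbf / 0.9, 0))
  }
  base <- lapply(c(0.4, 0.45, 0.5), mk_rec)
  acz <- lapply(c(0.55, 0.6, 0.63), mk_rec)
  rep3 <- run_case(3, base, acz)
  expect_equal(rep3$pct_change_input, rep3$pct_change_aif, tolerance = 1e-6)
  expect_error(run_case(3, base, acz[1:2]), "paired")
})

test_that("case 1 detects the acetazolamide CBF increase on the phantom", {
  fx <- small_cohort()
  rep1 <- run_case(1, fx$records$baseline, fx$records$acz)
  expect_lt(rep1$change_test_input$p_value, 0.05)
  expect_gt(rep1$pct_change_input, 0)
  expect_length(rep1$slopes, 12L)
  expect_type(rep1$slope_outliers, "logical")
  expect_true(all(rep1$gp_variance >= 0))
  # reports are deterministic
  rep1b <- run_case(1, fx$records$baseline, fx$records$acz)
  expect_equal(rep1$cbf_input, rep1b$cbf_input)
})

test_that("case 2 transfer model still separates the conditions", {
  fx <- small_cohort()
  rep2 <- run_case(2, fx$records$baseline, fx$records$acz)
  expect_lt(rep2$change_test_input$p_value, 0.05)
  expect_gt(rep2$pct_change_input, 0)
  expect_gt(rep2$agreement$baseline$mean_ratio, 0.8)
  expect_lt(rep2$agreement$baseline$mean_ratio, 1.2)
})
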