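# Shared fixtures: all built in code at test time.

# A smooth gamma-variate bolus on a uniform grid (the generic test input).
# `t0` is the arrival delay after injection (physiologically 20-30 s).
smooth_bolus <- function(t = 0:360, peak = 50, tp = 25, alpha = 3, t0 = 0) {
  u <- pmax(t - t0, 0)
  v <- peak * (u / tp)^alpha * exp(alpha * (1 - u / tp)) +
    0.1 * peak * (1 - exp(-u / 60)) * exp(-u / 200)
  v[u == 0] <- 0
  new_tac(t, v, grid_kind = "uniform")
}

# Tiny toy GP training set: 5 subjects, short curves.
toy_gp_set <- function(n = 5, d = 12, T = 20, seed = 404) {
  set.seed(seed)
  X <- matrix(runif(n * d), n, d)
  Y <- matrix(rnorm(n * T, mean = 10, sd = 2), n, T)
  list(X = X, Y = Y)
}

# Small processed phantom cohort, built once per test run and memoised.
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(6, seed = 301)
    .fixture_env$records <- process_cohort(.fixture_env$cohort)
  }
  list(cohort = .fixture_env$cohort, records = .fixture_env$records)
}

# Build a synthetic idif_set directly from three curves (bypasses imaging).
make_idif_set <- function(c10, c100, c1000) {
  structure(list(idif10 = c10, idif100 = c100, idif1000 = c1000,
                 threshold_frame = NA_integer_),
            class = "idif_set")
}
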