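#' Matern 5/2 covariance between input vectors
#'
#' k(r) = sf2 * (1 + a + a^2/3) * exp(-a), a = sqrt(5) r / ell, with r the
#' Euclidean distance between inputs. Sample paths are twice differentiable,
#' which suits smooth bolus curves.
#'
#' @param d2 Matrix of squared Euclidean distances.
#' @param ell Lengthscale, > 0.
#' @param sf2 Signal variance, > 0.
#' @return Covariance matrix, same shape as `d2`.
#' @keywords internal
matern52 <- function(d2, ell, sf2) {
  a <- sqrt(5 * pmax(d2, 0)) / ell
  sf2 * (1 + a + a^2 / 3) * exp(-a)
}

cross_dist2 <- function(A, B) {
  # squared Euclidean distances between rows of A and rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
}

#' Per-channel peak-normalisation constants
#'
#' For each IDIF channel, the largest peak value across the training cohort.
#' Dividing every curve of a channel by its cohort maximum maps training
#' inputs into \[0, 1\] while preserving relative amplitudes between
#' subjects (the normalisation is a pure scale factor).
#'
#' @param idif_list List of `idif_set` objects (training cohort).
#' @return Named numeric vector `c(peak10=, peak100=, peak1000=)`, all > 0.
#' @export
fit_normalization <- function(idif_list) {
  if (length(idif_list) == 0L) stop("empty training list")
  pk <- function(ch) max(vapply(idif_list, function(s) max(s[[ch]]$value),
                                numeric(1)))
  out <- c(peak10 = pk("idif10"), peak100 = pk("idif100"),
           peak1000 = pk("idif1000"))
  if (any(out <= 0)) stop("a channel is all-zero across the cohort")
  out
}

#' Normalise an IDIF set into a GP input vector
#'
#' Concatenates the three channels, each divided by its cohort peak
#' constant. Training inputs land in \[0, 1\]; test inputs may exceed 1,
#' which deliberately preserves domain shift.
#'
#' @param idifs An `idif_set`.
#' @param norm Constants from [fit_normalization()].
#' @return Numeric vector of length 3 * T.
#' @export
normalize_idifs <- function(idifs, norm) {
  if (any(norm <= 0)) stop("normalisation constants must be > 0")
  c(idifs$idif10$value / norm["peak10"],
    idifs$idif100$value / norm["peak100"],
    idifs$idif1000$value / norm["peak1000"])
}

gp_nll <- function(logp, D2, Y) {
  ell <- exp(logp[1]); sf2 <- exp(logp[2]); sn2 <- exp(logp[3])
  n <- nrow(D2); T <- ncol(Y)
  K <- matern52(D2, ell, sf2) + (sn2 + 1e-10 * sf2) * diag(n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), Y))
  0.5 * sum(Y * alpha) + T * sum(log(diag(L))) + n * T / 2 * log(2 * pi)
}

#' Train the Gaussian-process input-function model
#'
#' A zero-mean GP with a single isotropic Matern 5/2 kernel over the
#' 3T-dimensional normalised IDIF input, shared across the T output time
#' points of the arterial curve (the outputs form the columns of an N x T
#' matrix; see the predictive equations in [gp_predict()]). The lengthscale,
#' signal variance and noise variance maximise the log marginal likelihood
#' summed over output dimensions, via L-BFGS-B on log-parameters; the
#' Cholesky factor of (K + sn2 I) is cached. Training arterial outputs are
#' not normalised — their scale carries the calibration.
#'
#' The default initialisation is data-driven and deterministic: lengthscale
#' at the median pairwise training distance, signal variance at the mean
#' output variance, noise at 1% of it. A fixed off-scale start (e.g.
#' unit variance against kBq/mL outputs) can land in the degenerate
#' pure-noise optimum where the kernel collapses and every prediction is
#' the zero mean function.
#'
#' @param X N x D matrix of normalised IDIF input vectors (rows = subjects).
#' @param Y N x T matrix of arterial input functions (kBq/mL).
#' @param norm Normalisation constants used to build `X` (stored for test
#'   use).
#' @param init Named list `ell`, `sf2`, `sn2` of hyperparameter starts;
#'   `NULL` (default) uses the data-driven heuristic.
#' @param maxit,pgtol Optimiser controls.
#' @return An object of class `gp_mlif`.
#' @export
gp_train <- function(X, Y, norm, init = NULL, maxit = 1000, pgtol = 1e-6) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 2) stop("need at least 2 training subjects")
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ")
  D2 <- cross_dist2(X, X)
  if (is.null(init)) {
    ell0 <- stats::median(sqrt(D2[upper.tri(D2)]))
    if (!is.finite(ell0) || ell0 <= 0) ell0 <- 1
    sf20 <- mean(apply(Y, 2, stats::var))
    if (!is.finite(sf20) || sf20 <= 0) sf20 <- 1
    # deterministic multi-start over lengthscale scalings: the marginal
    # likelihood has a degenerate pure-noise optimum (ell -> 0) that a
    # single start can fall into
    starts <- lapply(c(0.3, 1, 3), function(f)
      list(ell = f * ell0, sf2 = sf20, sn2 = 0.01 * sf20))
  } else starts <- list(init)
  run_opt <- function(st) {
    logp0 <- log(c(st$ell, st$sf2, st$sn2))
    o <- stats::optim(logp0, gp_nll, D2 = D2, Y = Y, method = "L-BFGS-B",
                      lower = log(c(1e-3, 1e-6, 1e-8)),
                      upper = log(c(1e3, 1e4, 1e2)),
                      control = list(maxit = maxit, pgtol = pgtol))
    o$nll0 <- gp_nll(logp0, D2, Y)
    o
  }
  opts <- lapply(starts, run_opt)
  opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
  ell <- exp(opt$par[1]); sf2 <- exp(opt$par[2]); sn2 <- exp(opt$par[3])
  K <- matern52(D2, ell, sf2) + (sn2 + 1e-10 * sf2) * diag(nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), Y))
  structure(list(ell = ell, sf2 = sf2, sn2 = sn2, norm = norm,
                 X = X, Y = Y, L = L, alpha = alpha,
                 nll = opt$value, nll0 = opt$nll0,
                 convergence = opt$convergence),
            class = "gp_mlif")
}

#' @export
print.gp_mlif <- function(x, ...) {
  cat(sprintf(paste0("gp_mlif: N = %d subjects, input dim %d; Matern-5/2 ",
                     "ell = %.3g, sf2 = %.3g, sn2 = %.3g\n"),
              nrow(x$X), ncol(x$X), x$ell, x$sf2, x$sn2))
  invisible(x)
}

#' Predict the arterial input function for a new scan
#'
#' GP posterior at the test input x*:
#' mean E\[y*\] = k*' (K + sn2 I)^-1 Y (a k*-weighted combination of training
#' arterial curves) and variance
#' V\[y*\] = k(x*, x*) - k*' (K + sn2 I)^-1 k*, shared across output time
#' points in this single-kernel formulation. Solves use the cached Cholesky
#' factor.
#'
#' @param model A trained [gp_train()] model.
#' @param idifs An `idif_set` for the test scan (same grids as training), or
#'   a pre-built numeric input vector.
#' @param t Time grid for the returned curve; defaults to 0..T-1 s.
#' @return An object of class `mlif_prediction`: `mean` (uniform `tac`),
#'   `variance` (per-time-point, all equal), `kstar` weights.
#' @export
gp_predict <- function(model, idifs, t = NULL) {
  xs <- if (inherits(idifs, "idif_set"))
    normalize_idifs(idifs, model$norm) else as.numeric(idifs)
  if (length(xs) != ncol(model$X))
    stop("test input dimension does not match training inputs")
  d2 <- cross_dist2(matrix(xs, nrow = 1), model$X)
  kstar <- matern52(d2, model$ell, model$sf2)  # 1 x N
  mu <- as.numeric(kstar %*% model$alpha)
  v <- forwardsolve(t(model$L), as.numeric(kstar))
  vstar <- max(model$sf2 - sum(v^2), 0)
  T <- ncol(model$Y)
  if (is.null(t)) t <- seq(0, T - 1)
  structure(list(mean = new_tac(t, mu, grid_kind = "uniform"),
                 variance = rep(vstar, T),
                 kstar = as.numeric(kstar)),
            class = "mlif_prediction")
}

#' Leave-one-out cross-validated MLIF predictions
#'
#' For each scan in the cohort the normalisation constants are refit and the
#' GP retrained on the remaining N - 1 scans; the held-out scan is then
#' normalised with the training-fold constants (no information leaks from
#' the held-out arterial curve or blood sample) and predicted.
#'
#' @param cohort List of scans, each a list with elements `idifs`
#'   (an `idif_set`) and `aif` (a uniform `tac`).
#' @param init GP hyperparameter initialisation, see [gp_train()].
#' @return List of `mlif_prediction`s in cohort order.
#' @export
gp_loo <- function(cohort, init = NULL) {
  n <- length(cohort)
  if (n < 3) stop("leave-one-out needs a cohort of >= 3")
  tgrid <- cohort[[1]]$aif$t
  lapply(seq_len(n), function(i) {
    tr <- cohort[-i]
    norm <- fit_normalization(lapply(tr, `[[`, "idifs"))
    X <- t(vapply(tr, function(s) normalize_idifs(s$idifs, norm),
                  numeric(length(normalize_idifs(tr[[1]]$idifs, norm)))))
    Y <- t(vapply(tr, function(s) s$aif$value, numeric(length(tgrid))))
    m <- gp_train(X, Y, norm, init = init)
    gp_predict(m, cohort[[i]]$idifs, t = tgrid)
  })
}

#' Train a cohort-level MLIF model from scans
#'
#' Convenience wrapper: fits normalisation on the whole cohort, builds the
#' input/output matrices and trains the GP.
#'
#' @inheritParams gp_loo
#' @return A `gp_mlif` model.
#' @export
gp_train_cohort <- function(cohort,
                            init = NULL) {
  norm <- fit_normalization(lapply(cohort, `[[`, "idifs"))
  X <- t(vapply(cohort, function(s) normalize_idifs(s$idifs, norm),
                numeric(length(normalize_idifs(cohort[[1]]$idifs, norm)))))
  Y <- t(vapply(cohort, function(s) s$aif$value,
                numeric(length(cohort[[1]]$aif$value))))
  gp_train(X, Y, norm, init = init)
}
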