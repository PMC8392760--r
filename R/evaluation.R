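#' Orthogonal (total least squares) regression
#'
#' Fits y = a + b x minimising perpendicular distances, treating both
#' variables as equally noisy. The slope is the classic TLS solution
#' b = (syy - sxx + sqrt((syy - sxx)^2 + 4 sxy^2)) / (2 sxy); r^2 is the
#' squared Pearson correlation. Swapping x and y inverts the slope.
#'
#' @param x,y Paired numeric vectors, >= 3 points, x non-constant.
#' @return List with `slope`, `intercept`, `r2`.
#' @export
orthogonal_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need >= 3 paired points")
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 && syy == 0) stop("degenerate constant input")
  slope <- if (sxy == 0) {
    if (sxx >= syy) 0 else Inf
  } else {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (sxx == 0 || syy == 0) NA_real_ else stats::cor(x, y)^2
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' Flag outlying regression slopes by the scaled-MAD rule
#'
#' A slope is an outlier when it lies more than 3 scaled median absolute
#' deviations (MAD x 1.4826, the normal-consistency factor) from the median
#' slope. In the degenerate MAD = 0 case any value different from the
#' median is flagged (the limit of the rule).
#'
#' @param slopes Numeric vector (>= 3).
#' @param n_mad Threshold multiple (default 3).
#' @return Logical vector, TRUE = outlier.
#' @export
flag_slope_outliers <- function(slopes, n_mad = 3) {
  if (length(slopes) < 3) stop("need >= 3 slopes")
  med <- stats::median(slopes)
  smad <- 1.4826 * stats::median(abs(slopes - med))
  if (smad == 0) return(slopes != med)
  abs(slopes - med) > n_mad * smad
}

#' Bland-Altman agreement limits
#'
#' @param a,b Paired numeric vectors, n >= 2.
#' @return List with `bias` (mean of a - b), `loa_low`, `loa_high`
#'   (bias -/+ 1.96 SD of the differences).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("need >= 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Paired agreement report
#'
#' Two-sided paired t-test, mean ratio and Bland-Altman limits for two
#' paired measurement sets (e.g. MLIF-based vs arterial-sampling-based CBF).
#' For identical inputs the t statistic is 0 and p = 1 by convention.
#'
#' @param a,b Paired numeric vectors, n >= 2; `b` must be nonzero for ratios.
#' @return List with `bias`, `loa_low`, `loa_high`, `t_stat`, `p_value`,
#'   `mean_ratio` (mean of a_i / b_i).
#' @export
paired_comparison <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("need >= 2 pairs")
  if (any(b == 0)) stop("zero denominator in ratio calculation")
  ba <- bland_altman(a, b)
  d <- a - b
  if (stats::sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  c(ba, list(t_stat = t_stat, p_value = p, mean_ratio = mean(a / b)))
}

cbf_for_records <- function(records, inputs, config) {
  vapply(seq_along(records), function(i)
    fit_1tcm(records[[i]]$tissue, inputs[[i]], init = config$fit_init,
             lower = config$fit_lower, upper = config$fit_upper)$cbf,
    numeric(1))
}

curve_slopes <- function(preds, records, schedule) {
  vapply(seq_along(records), function(i) {
    a <- rebin_to_schedule(records[[i]]$aif, schedule)$value
    m <- rebin_to_schedule(preds[[i]]$mean, schedule)$value
    orthogonal_regression(a, m)$slope
  }, numeric(1))
}

#' Run one case of the evaluation design
#'
#' Three cases compare CBF derived with a predicted or image-derived input
#' function against CBF derived with the arterial input function, on paired
#' baseline/acetazolamide cohorts:
#' \describe{
#'   \item{case 1}{separate leave-one-out GP models per condition
#'     (baseline model tested on baseline, acetazolamide model on
#'     acetazolamide);}
#'   \item{case 2}{baseline via leave-one-out; the acetazolamide scans
#'     predicted by a model trained on all baseline scans (transfer);}
#'   \item{case 3}{no GP — the carotid IDIF10 curve is used directly as
#'     input function, to probe the brain-local versus wrist input
#'     difference.}
#' }
#' Each scan record must carry `idifs` (an `idif_set`), `aif` (the
#' dispersion/delay-corrected arterial `tac`) and `tissue` (the windowed
#' 1-s grey-matter `tac`).
#'
#' @param case_id 1, 2 or 3.
#' @param baseline,acz Paired lists of scan records (same subject order).
#' @param config Configuration list, see [default_config()].
#' @return A list report: per-condition CBF vectors for the tested input
#'   function (`cbf_input`) and the arterial reference (`cbf_aif`), the
#'   percentage change in mean CBF between conditions for both, the paired
#'   t-test of the change, per-condition agreement reports, and (cases 1-2)
#'   per-scan orthogonal-regression slopes of predicted-vs-arterial curve
#'   points on the original PET framing with scaled-MAD outlier flags.
#' @export
run_case <- function(case_id, baseline, acz, config = default_config()) {
  stopifnot(case_id %in% 1:3)
  if (length(baseline) != length(acz)) stop("cohorts must be paired")
  schedule <- default_frame_schedule()
  out <- list(case_id = case_id)

  if (case_id %in% c(1, 2)) {
    loo_base <- gp_loo(baseline, init = config$gp_init)
    preds_acz <- if (case_id == 1) {
      gp_loo(acz, init = config$gp_init)
    } else {
      model <- gp_train_cohort(baseline, init = config$gp_init)
      lapply(acz, function(s)
        gp_predict(model, s$idifs, t = s$aif$t))
    }
    in_base <- lapply(loo_base, `[[`, "mean")
    in_acz <- lapply(preds_acz, `[[`, "mean")
    slopes <- c(curve_slopes(loo_base, baseline, schedule),
                curve_slopes(preds_acz, acz, schedule))
    out$slopes <- slopes
    out$slope_outliers <- flag_slope_outliers(slopes)
    out$gp_variance <- c(vapply(loo_base, function(p) p$variance[1],
                                numeric(1)),
                         vapply(preds_acz, function(p) p$variance[1],
                                numeric(1)))
  } else {
    in_base <- lapply(baseline, function(s) s$idifs$idif10)
    in_acz <- lapply(acz, function(s) s$idifs$idif10)
  }

  cbf_in_base <- cbf_for_records(baseline, in_base, config)
  cbf_in_acz <- cbf_for_records(acz, in_acz, config)
  cbf_aif_base <- cbf_for_records(baseline, lapply(baseline, `[[`, "aif"),
                                  config)
  cbf_aif_acz <- cbf_for_records(acz, lapply(acz, `[[`, "aif"), config)

  out$cbf_input <- list(baseline = cbf_in_base, acz = cbf_in_acz)
  out$cbf_aif <- list(baseline = cbf_aif_base, acz = cbf_aif_acz)
  out$pct_change_input <-
    100 * (mean(cbf_in_acz) - mean(cbf_in_base)) / mean(cbf_in_base)
  out$pct_change_aif <-
    100 * (mean(cbf_aif_acz) - mean(cbf_aif_base)) / mean(cbf_aif_base)
  out$change_test_input <- paired_comparison(cbf_in_acz, cbf_in_base)
  out$change_test_aif <- paired_comparison(cbf_aif_acz, cbf_aif_base)
  if (case_id %in% c(1, 2)) {
    out$agreement <- list(
      baseline = paired_comparison(cbf_in_base, cbf_aif_base),
      acz = paired_comparison(cbf_in_acz, cbf_aif_acz))
    out$regression <- list(
      baseline = orthogonal_regression(cbf_aif_base, cbf_in_base),
      acz = orthogonal_regression(cbf_aif_acz, cbf_in_acz))
  }
  out
}
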