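# Causal-effect estimators for two-sample MR on harmonized instruments.
#
# Notation: per SNP j the harmonized set carries the SNP-exposure effect
# beta_exp (gamma-hat) with SE se_exp, and the SNP-outcome effect beta_out
# (Gamma-hat) with SE se_out. All estimators use first-order weights
# w_j = beta_exp_j^2 / se_out_j^2, i.e. weighted least squares of the
# outcome effects on the exposure effects.

new_mr_result <- function(h, method, nsnp, beta, se, pval, extras = list()) {
  ci <- to_odds_ratio(beta, se)
  structure(list(exposure = attr(h, "exposure_id") %||% "exposure",
                 outcome = attr(h, "outcome_id") %||% "outcome",
                 method = method, nsnp = nsnp,
                 beta = beta, se = se, pval = pval,
                 or = ci[["or"]], ci_low = ci[["ci_low"]],
                 ci_high = ci[["ci_high"]], extras = extras),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s: %d SNP(s), beta = %s (SE %s), p = %s, OR %s (95%% CI %s, %s)\n",
              x$method, x$nsnp,
              format(x$beta, digits = digits), format(x$se, digits = digits),
              format(x$pval, digits = 3),
              formatC(x$or, digits = 3, format = "f"),
              formatC(x$ci_low, digits = 3, format = "f"),
              formatC(x$ci_high, digits = 3, format = "f")))
  invisible(x)
}

#' Odds-ratio presentation of a log-scale estimate
#'
#' Exponentiates a causal estimate on the log-odds scale and its 95%
#' confidence bounds `exp(beta -/+ 1.96 * se)` (1.96 verbatim, matching
#' the conventional table presentation).
#'
#' @param beta log-scale estimate.
#' @param se its standard error (non-negative).
#' @return Named numeric vector `(or, ci_low, ci_high)`.
#' @examples
#' to_odds_ratio(0, 0.1)
#' @export
to_odds_ratio <- function(beta, se) {
  stopifnot(is.na(se) || se >= 0)
  c(or = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se))
}

#' Wald ratio estimate from a single instrument
#'
#' The per-SNP causal estimate `beta_out / beta_exp` with first-order
#' standard error `se_out / |beta_exp|` and a two-sided normal p-value.
#'
#' @param h an `mr_harmonized` set with exactly one kept row (a set with
#'   more rows uses only its first kept row).
#' @return An `mr_result`.
#' @export
mr_wald_ratio <- function(h) {
  d <- kept_rows(h)
  if (nrow(d) < 1) stop_mr("no kept rows", class = "insufficient_snps_error")
  d <- d[1, ]
  if (d$beta_exp == 0) {
    stop_mr("undefined Wald ratio: exposure effect is zero",
            class = "undefined_ratio_error")
  }
  beta <- d$beta_out / d$beta_exp
  se <- d$se_out / abs(d$beta_exp)
  new_mr_result(h, "wald_ratio", 1L, beta, se, p_from_z(beta / se))
}

# Fixed-effects IVW sums; shared by several routines.
ivw_sums <- function(d) {
  w <- d$beta_exp^2 / d$se_out^2
  ratio <- d$beta_out / d$beta_exp
  beta <- sum(w * ratio) / sum(w)
  list(w = w, ratio = ratio, beta = beta, se_fe = sqrt(1 / sum(w)),
       q = sum(w * (ratio - beta)^2))
}

#' Inverse-variance-weighted causal estimate
#'
#' The primary MR estimator: the inverse-variance-weighted average of the
#' per-SNP Wald ratios with first-order weights
#' `w_j = beta_exp_j^2 / se_out_j^2`, equivalent to weighted least squares
#' of the outcome effects on the exposure effects through the origin.
#' Under `effects = "fixed"` the SE is `1/sqrt(sum(w))`; the default
#' multiplicative random-effects model scales the SE by
#' `sqrt(max(1, Q/(k-1)))`, where Q is Cochran's heterogeneity statistic,
#' so heterogeneity widens but never narrows the interval. P-values are
#' two-sided normal. With one instrument the estimate reduces exactly to
#' the Wald ratio.
#'
#' @param h an `mr_harmonized` set with at least one kept row.
#' @param effects `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return An `mr_result`; `extras` carries Q, its df and p, and the
#'   applied variance scale factor.
#' @export
mr_ivw <- function(h, effects = c("random", "fixed")) {
  effects <- match.arg(effects)
  d <- kept_rows(h)
  k <- nrow(d)
  if (k < 1) stop_mr("IVW needs at least 1 instrument",
                     class = "insufficient_snps_error")
  s <- ivw_sums(d)
  phi <- if (k > 1 && effects == "random") max(1, s$q / (k - 1)) else 1
  se <- s$se_fe * sqrt(phi)
  new_mr_result(h, if (effects == "random") "ivw_re" else "ivw_fe",
                k, s$beta, se, p_from_z(s$beta / se),
                extras = list(q = s$q, q_df = k - 1,
                              q_pval = if (k > 1)
                                stats::pchisq(s$q, k - 1, lower.tail = FALSE)
                              else NA_real_,
                              scale = phi))
}

# Closed-form weighted regression with intercept of y on x, weights w,
# unit base variance; returns coefficients and their base variances.
wls_with_intercept <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  denom <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / denom
  intercept <- (swxx * swy - swx * swxy) / denom
  list(slope = slope, intercept = intercept,
       var_slope = sw / denom, var_intercept = swxx / denom,
       rss = sum(w * (y - intercept - slope * x)^2))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept, weights `1/se_out^2`, after orienting exposure effects to be
#' non-negative. The slope estimates the causal effect under the InSIDE
#' assumption even when all instruments are pleiotropic; the intercept
#' estimates the average directional pleiotropic effect. Standard errors
#' are scaled by `sqrt(max(1, Q_egger/(k-2)))` and inference uses the t
#' distribution with k-2 degrees of freedom.
#'
#' @param h an `mr_harmonized` set with at least 3 kept rows.
#' @return An `mr_result` for the slope; `extras` carries the intercept,
#'   its SE and p, the residual heterogeneity statistic `q` with df k-2,
#'   and the variance scale factor.
#' @export
mr_egger <- function(h) {
  d <- kept_rows(h)
  k <- nrow(d)
  if (k < 3) stop_mr("MR-Egger needs at least 3 instruments",
                     class = "insufficient_snps_error")
  flip <- d$beta_exp < 0
  d$beta_out[flip] <- -d$beta_out[flip]
  d$beta_exp[flip] <- -d$beta_exp[flip]
  fit <- wls_with_intercept(d$beta_exp, d$beta_out, 1 / d$se_out^2)
  phi <- max(1, fit$rss / (k - 2))
  se_slope <- sqrt(fit$var_slope * phi)
  se_int <- sqrt(fit$var_intercept * phi)
  new_mr_result(h, "egger", k, fit$slope, se_slope,
                p_from_t(fit$slope / se_slope, k - 2),
                extras = list(intercept = fit$intercept,
                              intercept_se = se_int,
                              intercept_pval = p_from_t(fit$intercept / se_int,
                                                        k - 2),
                              q = fit$rss, q_df = k - 2,
                              q_pval = stats::pchisq(fit$rss, k - 2,
                                                     lower.tail = FALSE),
                              scale = phi))
}

# Weighted 50th percentile of ratio estimates with midpoint interpolation.
weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  stats::approx(s, ratio, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Orders the per-SNP Wald ratios and takes the weighted 50th percentile
#' (inverse-variance weights, linear interpolation between the two ratios
#' whose cumulative midpoint weights bracket one half). Consistent as long
#' as valid instruments contribute more than half of the total weight,
#' which makes it the standard complement to IVW when some instruments
#' may be invalid. The SE comes from a seeded parametric bootstrap that
#' redraws both effect estimates from normal distributions with their
#' standard errors.
#'
#' @param h an `mr_harmonized` set with at least 3 kept rows.
#' @param n_boot bootstrap draws for the SE (0 skips the bootstrap and
#'   reports `NA` SE/p).
#' @param seed optional integer seed for the bootstrap.
#' @return An `mr_result`; `extras` records `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  d <- kept_rows(h)
  k <- nrow(d)
  if (k < 3) stop_mr("weighted median needs at least 3 instruments",
                     class = "insufficient_snps_error")
  w <- d$beta_exp^2 / d$se_out^2
  beta <- weighted_median_point(d$beta_out / d$beta_exp, w)
  se <- boot_se(d, n_boot, seed, function(be, bo, so)
    weighted_median_point(bo / be, be^2 / so^2))
  new_mr_result(h, "weighted_median", k, beta, se,
                if (is.na(se)) NA_real_ else p_from_z(beta / se),
                extras = list(n_boot = n_boot, seed = seed))
}

# Parametric bootstrap SE for order-statistic estimators.
boot_se <- function(d, n_boot, seed, point_fun) {
  if (n_boot <= 0) return(NA_real_)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(d)
  est <- vapply(seq_len(n_boot), function(i) {
    be <- stats::rnorm(k, d$beta_exp, d$se_exp)
    bo <- stats::rnorm(k, d$beta_out, d$se_out)
    point_fun(be, bo, d$se_out)
  }, numeric(1))
  stats::sd(est)
}

weighted_mode_point <- function(ratio, w, bandwidth_factor = 1) {
  if (length(unique(ratio)) == 1L) return(ratio[1])
  s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) *
    length(ratio)^(-1 / 5)
  if (s <= 0) s <- 0.9 * stats::sd(ratio) * length(ratio)^(-1 / 5)
  bw <- bandwidth_factor * s
  dens <- stats::density(ratio, weights = w / sum(w), bw = bw, n = 2048)
  dens$x[which.max(dens$y)]
}

#' Weighted-mode causal estimate
#'
#' The mode of the inverse-variance-weighted kernel-smoothed density of
#' the per-SNP Wald ratios (normal kernel; bandwidth is
#' `bandwidth_factor` times the modified Silverman rule
#' `0.9 * min(sd, mad) * k^(-1/5)` on the ratios). Consistent when the
#' largest group of instruments sharing a ratio value is valid, however
#' small its total weight. Bootstrap SE as in [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor multiplier on the modified Silverman
#'   bandwidth.
#' @return An `mr_result`.
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000,
                             seed = NULL) {
  d <- kept_rows(h)
  k <- nrow(d)
  if (k < 3) stop_mr("weighted mode needs at least 3 instruments",
                     class = "insufficient_snps_error")
  w <- d$beta_exp^2 / d$se_out^2
  beta <- weighted_mode_point(d$beta_out / d$beta_exp, w, bandwidth_factor)
  se <- boot_se(d, n_boot, seed, function(be, bo, so)
    weighted_mode_point(bo / be, be^2 / so^2, bandwidth_factor))
  new_mr_result(h, "weighted_mode", k, beta, se,
                if (is.na(se)) NA_real_ else p_from_z(beta / se),
                extras = list(n_boot = n_boot, seed = seed,
                              bandwidth_factor = bandwidth_factor))
}
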