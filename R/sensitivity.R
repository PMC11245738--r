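#' Cochran's Q heterogeneity statistic
#'
#' Heterogeneity of the per-SNP causal (Wald ratio) estimates around the
#' fitted model: `Q = sum(w_j * (ratio_j - model_j)^2)` with weights
#' `w_j = beta_exp_j^2 / se_out_j^2`. For `model = "ivw"` the reference is
#' the fixed-effects IVW estimate (df = k - 1); for `model = "egger"` it
#' is the fitted Egger line (df = k - 2). The p-value is the upper tail
#' of the chi-square distribution with the stated df; under homogeneity
#' Q has mean df, and a small p flags heterogeneous instruments.
#'
#' @param h an `mr_harmonized` set (k >= 2 for IVW, k >= 3 for Egger).
#' @param model `"ivw"` or `"egger"`.
#' @return Named numeric vector `(q, df, pval)`.
#' @export
cochran_q <- function(h, model = c("ivw", "egger")) {
  model <- match.arg(model)
  d <- kept_rows(h)
  k <- nrow(d)
  if (model == "ivw") {
    if (k < 2) stop_mr("Cochran's Q (IVW) needs k >= 2",
                       class = "insufficient_snps_error")
    s <- ivw_sums(d)
    q <- s$q
    df <- k - 1
  } else {
    if (k < 3) stop_mr("Cochran's Q (Egger) needs k >= 3",
                       class = "insufficient_snps_error")
    q <- mr_egger(h)$extras$q
    df <- k - 2
  }
  c(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the Egger regression estimates the average direct
#' (pleiotropic) effect of the instruments on the outcome; a two-sided t
#' test with k - 2 df against zero. An intercept p-value above the
#' significance level is taken as no evidence that directional pleiotropy
#' distorts the IVW estimate.
#'
#' @param h an `mr_harmonized` set with at least 3 kept rows.
#' @return Named numeric vector `(intercept, se, pval)`.
#' @export
egger_intercept_test <- function(h) {
  e <- mr_egger(h)$extras
  c(intercept = e$intercept, se = e$intercept_se, pval = e$intercept_pval)
}

# Leave-one-out fixed-effects IVW slopes for every SNP, O(k).
loo_slopes <- function(d) {
  a <- d$beta_exp * d$beta_out / d$se_out^2
  b <- d$beta_exp^2 / d$se_out^2
  (sum(a) - a) / (sum(b) - b)
}

#' MR-PRESSO outlier and distortion analysis
#'
#' Resampling-based detection of outlier instruments. The observed
#' residual sum of squares uses leave-one-out fixed-effects IVW slopes:
#' `RSS_j = (beta_out_j - b_(-j) * beta_exp_j)^2`, summed for the global
#' statistic. An empirical null is built from `n_sim` parametric
#' replicates drawing `beta_out*_j ~ N(b_(-j) * beta_exp_j, se_out_j^2)`
#' and `beta_exp*_j ~ N(beta_exp_j, se_exp_j^2)`; the global p-value is
#' `(1 + #\{RSS* >= RSS\}) / (n_sim + 1)` (the add-one rule, so p is never
#' zero). Per-SNP outlier p-values use the analogous per-SNP comparison
#' and are declared outliers below `outlier_alpha / k` (Bonferroni). The
#' distortion test compares the change in the IVW estimate after removing
#' the outliers against removals of random subsets of the same size.
#'
#' @param h an `mr_harmonized` set with at least 4 kept rows.
#' @param n_sim number of parametric null replicates (>= 1).
#' @param outlier_alpha family-wise level for outlier declaration.
#' @param seed optional integer seed.
#' @return An object of class `mr_presso`: list with `global_rss`,
#'   `global_pval`, `outlier_pvals` (named), `outliers`, `beta_before`,
#'   `beta_after`, `distortion_pval`, `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  d <- kept_rows(h)
  k <- nrow(d)
  if (k < 4) stop_mr("MR-PRESSO needs at least 4 instruments; skip it below that",
                     class = "insufficient_snps_error")
  if (n_sim < 1) stop_mr("n_sim must be >= 1", class = "config_error")
  if (!is.null(seed)) set.seed(seed)

  b_loo <- loo_slopes(d)
  rss_j <- (d$beta_out - b_loo * d$beta_exp)^2
  rss <- sum(rss_j)

  # parametric null replicates, vectorized over an n_sim x k matrix
  mu <- b_loo * d$beta_exp
  bo_star <- matrix(stats::rnorm(n_sim * k, rep(mu, each = n_sim),
                                 rep(d$se_out, each = n_sim)), n_sim, k)
  be_star <- matrix(stats::rnorm(n_sim * k, rep(d$beta_exp, each = n_sim),
                                 rep(d$se_exp, each = n_sim)), n_sim, k)
  inv_v <- rep(1 / d$se_out^2, each = n_sim)
  a_star <- be_star * bo_star * inv_v
  b_star <- be_star^2 * inv_v
  b_loo_star <- (rowSums(a_star) - a_star) / (rowSums(b_star) - b_star)
  rss_star_j <- (bo_star - b_loo_star * be_star)^2
  rss_star <- rowSums(rss_star_j)

  global_pval <- (1 + sum(rss_star >= rss)) / (n_sim + 1)
  outlier_pvals <- (1 + colSums(rss_star_j >=
                                  rep(rss_j, each = n_sim))) / (n_sim + 1)
  names(outlier_pvals) <- d$snp
  outliers <- d$snp[outlier_pvals < outlier_alpha / k]

  beta_before <- mr_ivw(h)$beta
  beta_after <- NA_real_
  distortion_pval <- NA_real_
  if (length(outliers) && length(outliers) < k - 1) {
    keep <- !(d$snp %in% outliers)
    h_sub <- subset_harmonized(h, d$snp[keep])
    beta_after <- mr_ivw(h_sub)$beta
    obs_diff <- abs(beta_before - beta_after)
    n_out <- length(outliers)
    null_diff <- vapply(seq_len(n_sim), function(i) {
      drop <- sample.int(k, n_out)
      hs <- subset_harmonized(h, d$snp[-drop])
      abs(beta_before - mr_ivw(hs)$beta)
    }, numeric(1))
    distortion_pval <- (1 + sum(null_diff >= obs_diff)) / (n_sim + 1)
  }
  structure(list(global_rss = rss, global_pval = global_pval,
                 outlier_pvals = outlier_pvals, outliers = outliers,
                 beta_before = beta_before, beta_after = beta_after,
                 distortion_pval = distortion_pval,
                 n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

# Restrict a harmonized set to the named kept SNPs (dropped rows removed).
subset_harmonized <- function(h, snps) {
  df <- as.data.frame(h)[h$snp %in% snps, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, exposure_id = attr(h, "exposure_id"),
            outcome_id = attr(h, "outcome_id"),
            n_exposure = attr(h, "n_exposure"),
            n_outcome = attr(h, "n_outcome"),
            class = class(h))
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.4g, global p = %.4g (%d sims)\n",
              x$global_rss, x$global_pval, x$n_sim))
  if (length(x$outliers)) {
    cat(sprintf("  outliers: %s\n  IVW before/after exclusion: %.4g / %.4g (distortion p = %.3g)\n",
                paste(x$outliers, collapse = ", "),
                x$beta_before, x$beta_after, x$distortion_pval))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the (random-effects) IVW causal effect k times, each time
#' omitting one instrument, to check that no single SNP drives the
#' result. With k = 2 each row reduces to the remaining SNP's Wald ratio.
#'
#' @param h an `mr_harmonized` set with at least 2 kept rows.
#' @return Data frame with columns `snp`, `beta`, `se`, `pval`;
#'   attributes `all_significant` (every leave-one-out p < 0.05),
#'   `min_snp`/`max_snp` flag the rows with the extreme estimates.
#' @export
leave_one_out <- function(h) {
  d <- kept_rows(h)
  k <- nrow(d)
  if (k < 2) stop_mr("leave-one-out needs at least 2 instruments",
                     class = "insufficient_snps_error")
  rows <- lapply(seq_len(k), function(j) {
    r <- mr_ivw(subset_harmonized(h, d$snp[-j]))
    data.frame(snp = d$snp[j], beta = r$beta, se = r$se, pval = r$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "all_significant") <- all(out$pval < 0.05)
  attr(out, "min_snp") <- out$snp[which.min(out$beta)]
  attr(out, "max_snp") <- out$snp[which.max(out$beta)]
  out
}

#' Steiger directionality test
#'
#' Guards against reverse causation by comparing the variance the
#' instruments explain in the exposure versus the outcome. Per SNP,
#' `r2 = t^2 / (t^2 + n - 2)` with `t = beta/se` on each side; the sums
#' over instruments give `r2_exp` and `r2_out`. The causal direction is
#' supported (`direction = TRUE`) when `r2_exp > r2_out`; the p-value is
#' the two-sided Fisher-z comparison of `atanh(sqrt(r2))` between the two
#' samples. For a binary outcome the log-odds associations are treated as
#' continuous-scale correlations (an approximation).
#'
#' @param h an `mr_harmonized` set with at least 1 kept row.
#' @param n_exposure,n_outcome GWAS sample sizes (> 3); default to the
#'   values recorded on the harmonized set.
#' @return Named list `(r2_exp, r2_out, direction, pval)`.
#' @export
steiger_test <- function(h, n_exposure = attr(h, "n_exposure"),
                         n_outcome = attr(h, "n_outcome")) {
  d <- kept_rows(h)
  if (nrow(d) < 1) stop_mr("Steiger test needs at least 1 instrument",
                           class = "insufficient_snps_error")
  if (is.null(n_exposure) || is.na(n_exposure) || n_exposure <= 3 ||
      is.null(n_outcome) || is.na(n_outcome) || n_outcome <= 3) {
    stop_mr("Steiger test needs sample sizes > 3 on both sides",
            class = "config_error")
  }
  r2_one <- function(beta, se, n) {
    t2 <- (beta / se)^2
    sum(t2 / (t2 + n - 2))
  }
  r2_exp <- r2_one(d$beta_exp, d$se_exp, n_exposure)
  r2_out <- r2_one(d$beta_out, d$se_out, n_outcome)
  cap <- function(r2) min(sqrt(max(r2, 0)), 1 - 1e-12)
  z <- (atanh(cap(r2_exp)) - atanh(cap(r2_out))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  list(r2_exp = r2_exp, r2_out = r2_out,
       direction = r2_exp > r2_out, pval = p_from_z(z))
}

#' Run the full sensitivity suite
#'
#' Bundles Cochran's Q (IVW and Egger), the Egger intercept test,
#' [mr_presso()], [leave_one_out()] and [steiger_test()] into one report
#' feeding the classification workflow. Components whose minimum
#' instrument count is not met are recorded as skipped rather than
#' failing the whole report.
#'
#' @inheritParams mr_presso
#' @inheritParams steiger_test
#' @return An object of class `mr_sensitivity`: list with elements
#'   `q_ivw`, `q_egger`, `egger_intercept`, `presso`, `loo`, `steiger`,
#'   `skipped`.
#' @export
mr_sensitivity <- function(h, n_sim = 1000, outlier_alpha = 0.05,
                           seed = NULL,
                           n_exposure = attr(h, "n_exposure"),
                           n_outcome = attr(h, "n_outcome")) {
  k <- nrow(kept_rows(h))
  skipped <- character()
  run <- function(min_k, name, fun) {
    if (k < min_k) {
      skipped <<- c(skipped, name)
      NULL
    } else {
      fun()
    }
  }
  out <- list(
    q_ivw = run(2, "q_ivw", function() cochran_q(h, "ivw")),
    q_egger = run(3, "q_egger", function() cochran_q(h, "egger")),
    egger_intercept = run(3, "egger_intercept",
                          function() egger_intercept_test(h)),
    presso = run(4, "presso", function()
      mr_presso(h, n_sim = n_sim, outlier_alpha = outlier_alpha,
                seed = seed)),
    loo = run(2, "loo", function() leave_one_out(h)),
    steiger = run(1, "steiger", function()
      steiger_test(h, n_exposure, n_outcome)))
  out$skipped <- skipped
  structure(out, class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("MR sensitivity report\n")
  if (!is.null(x$q_ivw)) {
    cat(sprintf("  Q (IVW):   %.3f on %d df, p = %.3g\n", x$q_ivw[["q"]],
                as.integer(x$q_ivw[["df"]]), x$q_ivw[["pval"]]))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept: %.4g, p = %.3g\n",
                x$egger_intercept[["intercept"]],
                x$egger_intercept[["pval"]]))
  }
  if (!is.null(x$presso)) {
    cat(sprintf("  PRESSO global p: %.4g; outliers: %s\n",
                x$presso$global_pval,
                if (length(x$presso$outliers))
                  paste(x$presso$outliers, collapse = ", ") else "none"))
  }
  if (!is.null(x$loo)) {
    cat(sprintf("  Leave-one-out: all p < 0.05: %s\n",
                attr(x$loo, "all_significant")))
  }
  if (!is.null(x$steiger)) {
    cat(sprintf("  Steiger: r2_exp = %.4g, r2_out = %.4g, direction %s (p = %.3g)\n",
                x$steiger$r2_exp, x$steiger$r2_out,
                if (x$steiger$direction) "supported" else "reversed",
                x$steiger$pval))
  }
  if (length(x$skipped)) {
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
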