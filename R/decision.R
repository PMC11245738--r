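#' Classify a single exposure-outcome association
#'
#' Applies the analysis decision tree to the estimator results and the
#' sensitivity report, in order: (1) fewer instruments than the method
#' minima require gives `insufficient_instruments`; (2) a failed Steiger
#' direction gives `direction_failed`; (3) pleiotropy is declared when
#' the Egger intercept p is below `alpha` (under the
#' `"egger_or_presso"` policy, also when the PRESSO global p is below
#' `alpha`), heterogeneity when the IVW Cochran's Q p is below `alpha`;
#' (4) pleiotropy without heterogeneity prefers the Egger estimate
#' (`egger_preferred`); (5) heterogeneity without pleiotropy keeps the
#' random-effects IVW estimate (`heterogeneity_adjusted`, the weighted
#' median is reported alongside); (6) with neither, a significant IVW
#' p and a consistent direction of the IVW/Egger/weighted-median
#' estimates gives `robust_positive`, even if the supplementary methods
#' are themselves non-significant; (7) anything else is
#' `not_significant`. The classification is a pure function of the
#' recorded evidence booleans and can be re-derived from them.
#'
#' @param ivw,egger,wmedian `mr_result` objects from the same harmonized
#'   set (any may be `NULL` when not computable).
#' @param report an `mr_sensitivity` report for the same set.
#' @param alpha significance level for every rule (default 0.05).
#' @param policy `"egger_only"` (default) or `"egger_or_presso"`:
#'   whether the PRESSO global test joins the pleiotropy verdict.
#' @return An object of class `mr_decision`: list with `exposure`,
#'   `outcome`, `classification`, `primary` (the preferred `mr_result`),
#'   `evidence` (named logical record) and `alpha`/`policy`.
#' @export
classify_association <- function(ivw, egger, wmedian, report, alpha = 0.05,
                                 policy = c("egger_only", "egger_or_presso")) {
  policy <- match.arg(policy)
  have_all <- !is.null(ivw) && !is.null(egger) && !is.null(wmedian) &&
    !is.null(report$q_ivw) && !is.null(report$egger_intercept)
  evidence <- list(
    ivw_significant = if (!is.null(ivw)) ivw$pval < alpha else NA,
    heterogeneity = if (!is.null(report$q_ivw))
      unname(report$q_ivw[["pval"]] < alpha) else NA,
    pleiotropy = if (!is.null(report$egger_intercept)) {
      p <- unname(report$egger_intercept[["pval"]] < alpha)
      if (policy == "egger_or_presso" && !is.null(report$presso)) {
        p <- p || report$presso$global_pval < alpha
      }
      p
    } else NA,
    directions_consistent = if (have_all) {
      length(unique(sign(c(ivw$beta, egger$beta, wmedian$beta)))) == 1L
    } else NA,
    steiger_ok = if (!is.null(report$steiger)) report$steiger$direction else NA,
    loo_all_significant = if (!is.null(report$loo))
      attr(report$loo, "all_significant") else NA)

  decide <- function(classification, primary, significant = NA) {
    structure(list(exposure = primary$exposure %||% NA_character_,
                   outcome = primary$outcome %||% NA_character_,
                   classification = classification, primary = primary,
                   evidence = c(evidence, primary_significant = significant),
                   alpha = alpha, policy = policy),
              class = "mr_decision")
  }
  if (!have_all) return(decide("insufficient_instruments", ivw))
  if (!isTRUE(evidence$steiger_ok)) return(decide("direction_failed", ivw))
  if (evidence$pleiotropy && !evidence$heterogeneity) {
    return(decide("egger_preferred", egger, egger$pval < alpha))
  }
  if (evidence$heterogeneity && !evidence$pleiotropy) {
    return(decide("heterogeneity_adjusted", ivw, ivw$pval < alpha))
  }
  if (!evidence$pleiotropy && !evidence$heterogeneity &&
      evidence$ivw_significant && evidence$directions_consistent) {
    return(decide("robust_positive", ivw, TRUE))
  }
  decide("not_significant", ivw, FALSE)
}

#' @export
print.mr_decision <- function(x, ...) {
  cat(sprintf("%s -> %s: %s\n", x$exposure, x$outcome, x$classification))
  if (!is.null(x$primary)) print(x$primary)
  ev <- x$evidence
  cat("  evidence:",
      paste(sprintf("%s=%s", names(ev), unlist(ev)), collapse = ", "), "\n")
  invisible(x)
}

#' Run the full per-pair MR analysis
#'
#' The complete pipeline for one exposure-outcome pair: instrument
#' selection, harmonization, all estimators, the sensitivity suite,
#' a single PRESSO outlier-exclusion re-run when outliers are found,
#' and the final classification. Every stage's counts and seeds are
#' recorded in a structured log.
#'
#' @param exposure a [summary_dataset] (or path to a sumstats TSV read
#'   with default columns as a continuous trait).
#' @param outcome a [summary_dataset] (or path, read as a binary trait).
#' @param ld an [ld_matrix] (or path to a square LD TSV).
#' @param p_threshold,window_bp,r2_threshold,f_threshold instrument
#'   selection thresholds, see [select_instruments()].
#' @param eaf_tolerance palindromic ambiguity window half-width.
#' @param alpha significance level for the decision rules.
#' @param policy pleiotropy policy, see [classify_association()].
#' @param n_boot bootstrap draws for median/mode SEs.
#' @param presso_n_sim PRESSO null replicates.
#' @param seed integer seed covering every stochastic component.
#' @return An object of class `mr_analysis`: list with `instruments`,
#'   `harmonized`, `fit` (pre-exclusion [mr_fit]), `sensitivity`,
#'   `fit_final`/`sensitivity_final` (post-exclusion, identical to the
#'   former when no outliers), `decision` and `log`.
#' @export
run_full_analysis <- function(exposure, outcome, ld,
                              p_threshold = 1e-5, window_bp = 500000,
                              r2_threshold = 0.001, f_threshold = 10,
                              eaf_tolerance = 0.08, alpha = 0.05,
                              policy = c("egger_only", "egger_or_presso"),
                              n_boot = 1000, presso_n_sim = 1000,
                              seed = 1L) {
  policy <- match.arg(policy)
  if (is.character(exposure)) {
    exposure <- read_sumstats(exposure, trait_id = exposure,
                              trait_type = "continuous")
  }
  if (is.character(outcome)) {
    outcome <- read_sumstats(outcome, trait_id = outcome,
                             trait_type = "binary")
  }
  if (is.character(ld)) ld <- read_ld_matrix(ld)

  iv <- select_instruments(exposure, ld, p_threshold, window_bp,
                           r2_threshold, f_threshold)
  h <- harmonize_pair(iv, outcome, eaf_tolerance)
  k <- nrow(kept_rows(h))
  log <- list(n_input = nrow(exposure), n_instruments = nrow(iv$data),
              n_harmonized = k, seed = seed,
              harmonize_actions = table(h$action),
              presso_excluded = character())

  fit <- if (k >= 1) mr_fit(h, n_boot = n_boot, seed = seed) else NULL
  sens <- if (k >= 1) mr_sensitivity(h, n_sim = presso_n_sim, seed = seed)
          else NULL

  h_final <- h
  fit_final <- fit
  sens_final <- sens
  # a single outlier-exclusion pass: identified outliers leave the analysis
  if (!is.null(sens) && !is.null(sens$presso) &&
      length(sens$presso$outliers)) {
    keep <- setdiff(kept_rows(h)$snp, sens$presso$outliers)
    if (length(keep) >= 1) {
      h_final <- subset_harmonized(h, keep)
      fit_final <- mr_fit(h_final, n_boot = n_boot, seed = seed)
      sens_final <- mr_sensitivity(h_final, n_sim = presso_n_sim,
                                   seed = seed)
      log$presso_excluded <- sens$presso$outliers
    }
  }
  log$n_final <- nrow(kept_rows(h_final))

  decision <- classify_association(
    ivw = fit_final$details$ivw,
    egger = fit_final$details$egger,
    wmedian = fit_final$details$weighted_median,
    report = sens_final %||% list(), alpha = alpha, policy = policy)
  if (is.null(fit_final$details$ivw)) {
    decision$exposure <- attr(exposure, "trait_id")
    decision$outcome <- attr(outcome, "trait_id")
  }
  structure(list(instruments = iv, harmonized = h, fit = fit,
                 sensitivity = sens, harmonized_final = h_final,
                 fit_final = fit_final, sensitivity_final = sens_final,
                 decision = decision, log = log),
            class = "mr_analysis")
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat(sprintf("MR analysis: %d candidate SNPs -> %d instruments -> %d harmonized -> %d final\n",
              x$log$n_input, x$log$n_instruments, x$log$n_harmonized,
              x$log$n_final))
  if (length(x$log$presso_excluded)) {
    cat("  PRESSO exclusions:",
        paste(x$log$presso_excluded, collapse = ", "), "\n")
  }
  print(x$decision)
  invisible(x)
}

#' Robust overlap of exposures across several outcomes
#'
#' Computes, per outcome, the set of exposures with a robust association
#' and intersects the sets: an exposure enters the intersection only if
#' it is robust for every outcome with the same effect direction
#' throughout (the multi-outcome consistency logic behind Venn-style
#' summaries).
#'
#' @param decisions named list (one element per outcome, >= 2) of lists
#'   of `mr_decision` objects.
#' @param include_adjusted if `TRUE`, `egger_preferred` and
#'   `heterogeneity_adjusted` calls with a significant primary p also
#'   count as robust; by default only `robust_positive` does.
#' @return An object of class `mr_overlap`: list with `outcome_ids`,
#'   `per_outcome_robust` (named list of exposure sets) and
#'   `intersection`.
#' @export
overlap_robust <- function(decisions, include_adjusted = FALSE) {
  if (length(decisions) < 2) {
    stop_mr("overlap needs at least 2 outcomes", class = "config_error")
  }
  robust_of <- function(dlist) {
    keep <- vapply(dlist, function(d) {
      d$classification == "robust_positive" ||
        (include_adjusted &&
           d$classification %in% c("egger_preferred",
                                   "heterogeneity_adjusted") &&
           isTRUE(d$evidence$primary_significant))
    }, logical(1))
    vapply(dlist[keep], `[[`, character(1), "exposure")
  }
  per_outcome <- lapply(decisions, robust_of)
  inter <- Reduce(intersect, per_outcome)
  # direction consistency across outcomes
  if (length(inter)) {
    sign_of <- function(dlist, exposure) {
      for (d in dlist) if (d$exposure == exposure) return(sign(d$primary$beta))
      NA_real_
    }
    consistent <- vapply(inter, function(e) {
      s <- vapply(decisions, sign_of, numeric(1), exposure = e)
      length(unique(s)) == 1L
    }, logical(1))
    inter <- inter[consistent]
  }
  structure(list(outcome_ids = names(decisions) %||%
                   seq_along(decisions),
                 per_outcome_robust = per_outcome,
                 intersection = inter),
            class = "mr_overlap")
}

#' @export
print.mr_overlap <- function(x, ...) {
  cat("Robust exposures per outcome:\n")
  for (i in seq_along(x$per_outcome_robust)) {
    cat(sprintf("  %s: %s\n", x$outcome_ids[i],
                paste(x$per_outcome_robust[[i]], collapse = ", ")))
  }
  cat("Intersection:",
      if (length(x$intersection)) paste(x$intersection, collapse = ", ")
      else "(empty)", "\n")
  invisible(x)
}
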