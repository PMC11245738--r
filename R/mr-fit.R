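#' Fit two-sample Mendelian randomization models
#'
#' The central fitting function: runs the requested causal estimators on
#' a harmonized instrument set and returns a classed model object with
#' the usual accessor methods (`print`, `summary`, `coef`, `confint`,
#' `residuals`, `plot`). `summary()` additionally reports Cochran's Q for
#' the IVW and Egger models and the Egger intercept test.
#'
#' @param h an `mr_harmonized` set from [harmonize_pair()] or
#'   [harmonized_set()].
#' @param methods estimators to run, a subset of `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"weighted_mode"`, `"wald_ratio"`. Estimators
#'   whose minimum instrument count exceeds the data are skipped with a
#'   note in `$skipped`.
#' @param effects IVW effects model, `"random"` or `"fixed"`.
#' @param n_boot bootstrap draws for median/mode standard errors.
#' @param bandwidth_factor bandwidth multiplier for the weighted mode.
#' @param seed seed for the bootstrap estimators.
#' @return An object of class `mr_fit`: list with `results` (one row per
#'   method: exposure, outcome, method, nsnp, beta, se, pval, or,
#'   ci_low, ci_high), `details` (the full `mr_result` objects), `data`,
#'   `skipped` and `call`.
#' @examples
#' study <- simulate_study(sim_config(n_snps = 30, beta_causal = 0.1, seed = 2))
#' h <- harmonize_pair(study$exposure, study$outcome)
#' fit <- mr_fit(h, n_boot = 100, seed = 1)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(h, methods = c("ivw", "egger", "weighted_median",
                                  "weighted_mode"),
                   effects = c("random", "fixed"), n_boot = 1000,
                   bandwidth_factor = 1, seed = NULL) {
  effects <- match.arg(effects)
  methods <- match.arg(methods, c("ivw", "egger", "weighted_median",
                                  "weighted_mode", "wald_ratio"),
                       several.ok = TRUE)
  k <- nrow(kept_rows(h))
  runners <- list(
    wald_ratio = function() mr_wald_ratio(h),
    ivw = function() mr_ivw(h, effects = effects),
    egger = function() mr_egger(h),
    weighted_median = function() mr_weighted_median(h, n_boot = n_boot,
                                                    seed = seed),
    weighted_mode = function() mr_weighted_mode(h, bandwidth_factor,
                                                n_boot = n_boot, seed = seed))
  minima <- c(wald_ratio = 1L, ivw = 1L, egger = 3L,
              weighted_median = 3L, weighted_mode = 3L)
  details <- list()
  skipped <- character()
  for (m in methods) {
    if (k < minima[[m]]) {
      skipped <- c(skipped, m)
      next
    }
    details[[m]] <- runners[[m]]()
  }
  results <- as_mr_result_table(details)
  rownames(results) <- NULL
  structure(list(results = results, details = details, data = h,
                 skipped = skipped, nsnp = k, call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %s on %s (%d instruments)\n\n",
              attr(x$data, "exposure_id"), attr(x$data, "outcome_id"),
              x$nsnp))
  if (nrow(x$results)) {
    df <- x$results
    df$beta <- signif(df$beta, digits)
    df$se <- signif(df$se, digits)
    df$pval <- signif(df$pval, 3)
    df$`OR (95% CI)` <- sprintf("%.3f (%.3f, %.3f)", df$or, df$ci_low,
                                df$ci_high)
    print(df[c("method", "nsnp", "beta", "se", "pval", "OR (95% CI)")],
          row.names = FALSE)
  }
  if (length(x$skipped)) {
    cat("skipped (too few instruments):",
        paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$results$beta, object$results$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  df <- object$results
  if (!missing(parm)) df <- df[df$method %in% parm, , drop = FALSE]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(df$beta - z * df$se, df$beta + z * df$se)
  dimnames(out) <- list(df$method,
                        sprintf("%g %%", c((1 - level) / 2,
                                           1 - (1 - level) / 2) * 100))
  out
}

#' @export
residuals.mr_fit <- function(object, method = "ivw", ...) {
  d <- kept_rows(object$data)
  beta <- object$details[[method]]$beta %||%
    stop_mr("method '", method, "' not in fit", class = "method_error")
  stats::setNames((d$beta_out - beta * d$beta_exp) / d$se_out, d$snp)
}

#' @export
summary.mr_fit <- function(object, ...) {
  d <- kept_rows(object$data)
  k <- nrow(d)
  structure(list(fit = object,
                 q_ivw = if (k >= 2) cochran_q(object$data, "ivw"),
                 q_egger = if (k >= 3) cochran_q(object$data, "egger"),
                 intercept = if (k >= 3) egger_intercept_test(object$data)),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nHeterogeneity and pleiotropy:\n")
  if (!is.null(x$q_ivw)) {
    cat(sprintf("  Cochran's Q (IVW):   Q = %.3f, df = %d, p = %.3g\n",
                x$q_ivw[["q"]], as.integer(x$q_ivw[["df"]]),
                x$q_ivw[["pval"]]))
  }
  if (!is.null(x$q_egger)) {
    cat(sprintf("  Cochran's Q (Egger): Q = %.3f, df = %d, p = %.3g\n",
                x$q_egger[["q"]], as.integer(x$q_egger[["df"]]),
                x$q_egger[["pval"]]))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  Egger intercept:     %.4g (SE %.4g), p = %.3g\n",
                x$intercept[["intercept"]], x$intercept[["se"]],
                x$intercept[["pval"]]))
  }
  invisible(x)
}

#' @export
plot.mr_fit <- function(x, ...) {
  d <- kept_rows(x$data)
  graphics::plot(d$beta_exp, d$beta_out,
                 xlab = "SNP effect on exposure (per 1 SD)",
                 ylab = "SNP effect on outcome",
                 pch = 19, col = "grey30", ...)
  graphics::segments(d$beta_exp, d$beta_out - 1.96 * d$se_out,
                     d$beta_exp, d$beta_out + 1.96 * d$se_out,
                     col = "grey70")
  graphics::segments(d$beta_exp - 1.96 * d$se_exp, d$beta_out,
                     d$beta_exp + 1.96 * d$se_exp, d$beta_out,
                     col = "grey70")
  cols <- c(ivw = "firebrick", egger = "steelblue",
            weighted_median = "darkgreen", weighted_mode = "orange")
  for (m in names(x$details)) {
    det <- x$details[[m]]
    intercept <- det$extras$intercept %||% 0
    graphics::abline(intercept, det$beta, col = cols[[m]] %||% "black")
  }
  graphics::legend("topleft", legend = names(x$details),
                   col = vapply(names(x$details),
                                function(m) cols[[m]] %||% "black",
                                character(1)),
                   lty = 1, bty = "n")
  invisible(x)
}
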