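#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so strand cannot be
#' resolved from the alleles alone.
#'
#' @param effect_allele,other_allele single-base alleles (vectorized).
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  (effect_allele == "A" & other_allele == "T") |
    (effect_allele == "T" & other_allele == "A") |
    (effect_allele == "C" & other_allele == "G") |
    (effect_allele == "G" & other_allele == "C")
}

complement_allele <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

#' Construct a harmonized instrument set directly
#'
#' Builds the per-SNP (beta_exp, se_exp, beta_out, se_out) table all MR
#' estimators consume, e.g. from effect estimates obtained elsewhere.
#' Rows are canonically oriented so that `beta_exp >= 0` (flipping both
#' betas and complementing both frequencies where needed); the causal
#' estimators are invariant under this choice, and it makes the ordering
#' used by the weighted median/mode well defined.
#'
#' @param snp SNP ids (unique).
#' @param beta_exp,se_exp SNP-exposure effects and standard errors.
#' @param beta_out,se_out SNP-outcome effects and standard errors.
#' @param eaf_exp,eaf_out optional effect-allele frequencies.
#' @param action per-row harmonization action; defaults to `"kept"`.
#' @param exposure_id,outcome_id trait labels carried into results.
#' @param n_exposure,n_outcome optional sample sizes (used by the Steiger
#'   directionality test).
#' @return An object of class `mr_harmonized` (a data frame).
#' @export
harmonized_set <- function(snp, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NA_real_, eaf_out = NA_real_,
                           action = "kept",
                           exposure_id = "exposure", outcome_id = "outcome",
                           n_exposure = NA_real_, n_outcome = NA_real_) {
  df <- data.frame(snp = snp, beta_exp = beta_exp, se_exp = se_exp,
                   beta_out = beta_out, se_out = se_out,
                   eaf_exp = eaf_exp, eaf_out = eaf_out,
                   action = action, stringsAsFactors = FALSE)
  if (anyDuplicated(df$snp)) {
    stop_mr("duplicate snp ids in harmonized set", class = "duplicate_snp_error")
  }
  used <- df$action %in% c("kept", "flipped")
  if (any(used & (!is.finite(df$beta_exp) | !is.finite(df$beta_out) |
                    !is.finite(df$se_exp) | df$se_exp <= 0 |
                    !is.finite(df$se_out) | df$se_out <= 0))) {
    stop_mr("kept rows must have finite effects and positive SEs",
            class = "invariant_error")
  }
  flip <- used & df$beta_exp < 0
  df$beta_exp[flip] <- -df$beta_exp[flip]
  df$beta_out[flip] <- -df$beta_out[flip]
  df$eaf_exp[flip] <- 1 - df$eaf_exp[flip]
  df$eaf_out[flip] <- 1 - df$eaf_out[flip]
  rownames(df) <- NULL
  structure(df, exposure_id = exposure_id, outcome_id = outcome_id,
            n_exposure = n_exposure, n_outcome = n_outcome,
            class = c("mr_harmonized", "data.frame"))
}

# Rows actually used by estimators.
kept_rows <- function(h) {
  as.data.frame(h)[h$action %in% c("kept", "flipped"), , drop = FALSE]
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns each instrument SNP's outcome record onto the exposure's effect
#' allele. Per SNP: missing from the outcome drops the row
#' (`dropped_missing`); a direct allele match is kept; a swapped
#' effect/other match sign-flips the outcome beta (`flipped`); otherwise
#' the outcome alleles are strand-complemented and the two rules retried.
#' Palindromic (A/T, C/G) SNPs cannot be resolved by alleles: when either
#' frequency is missing or the exposure frequency is inside the ambiguity
#' window `(0.5 - eaf_tolerance, 0.5 + eaf_tolerance)` they are dropped
#' (`dropped_palindromic`); with informative frequencies on both sides
#' they are aligned so the frequencies agree. Irreconcilable allele pairs
#' are `dropped_allele_mismatch`. Kept rows are then canonically oriented
#' so `beta_exp >= 0` (see [harmonized_set()]).
#'
#' @param exposure an `instrument_set` from [select_instruments()] or a
#'   [summary_dataset] of instruments.
#' @param outcome a [summary_dataset] for the outcome trait.
#' @param eaf_tolerance half-width of the palindromic ambiguity window
#'   around 0.5 (default 0.08, the prevailing two-sample MR convention).
#' @return An `mr_harmonized` data frame with one row per instrument SNP
#'   and an `action` column; only `kept`/`flipped` rows enter estimation.
#' @export
harmonize_pair <- function(exposure, outcome, eaf_tolerance = 0.08) {
  exp_data <- if (inherits(exposure, "instrument_set")) exposure$data else exposure
  k <- nrow(exp_data)
  m <- match(exp_data$snp, outcome$snp)

  beta_out <- outcome$beta[m]
  se_out <- outcome$se[m]
  eaf_out <- outcome$eaf[m]
  ea_o <- outcome$effect_allele[m]
  oa_o <- outcome$other_allele[m]
  ea_e <- exp_data$effect_allele
  oa_e <- exp_data$other_allele

  action <- rep(NA_character_, k)
  action[is.na(m)] <- "dropped_missing"
  pal <- !is.na(m) & is_palindromic(ea_e, oa_e)

  # non-palindromic: direct / swapped / strand-complemented match
  idx <- which(!is.na(m) & !pal)
  for (i in idx) {
    res <- align_alleles(ea_e[i], oa_e[i], ea_o[i], oa_o[i])
    if (is.na(res)) {
      action[i] <- "dropped_allele_mismatch"
    } else if (res) {
      action[i] <- "flipped"
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    } else {
      action[i] <- "kept"
    }
  }

  # palindromic: same pair required; orientation by frequency agreement
  for (i in which(pal)) {
    same_pair <- (ea_o[i] %in% c(ea_e[i], oa_e[i])) &&
      (oa_o[i] %in% c(ea_e[i], oa_e[i])) && ea_o[i] != oa_o[i]
    if (!same_pair) {
      action[i] <- "dropped_allele_mismatch"
      next
    }
    fe <- exp_data$eaf[i]
    fo <- eaf_out[i]
    ambiguous <- is.na(fe) || is.na(fo) ||
      min(fe, 1 - fe) > 0.5 - eaf_tolerance
    if (ambiguous) {
      action[i] <- "dropped_palindromic"
    } else if ((fe < 0.5) == (fo < 0.5)) {
      action[i] <- "kept"
    } else {
      action[i] <- "flipped"
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    }
  }

  harmonized_set(snp = exp_data$snp,
                 beta_exp = exp_data$beta, se_exp = exp_data$se,
                 beta_out = beta_out, se_out = se_out,
                 eaf_exp = exp_data$eaf, eaf_out = eaf_out,
                 action = action,
                 exposure_id = attr(exp_data, "trait_id") %||% "exposure",
                 outcome_id = attr(outcome, "trait_id") %||% "outcome",
                 n_exposure = dataset_n(exp_data),
                 n_outcome = dataset_n(outcome))
}

# TRUE = flip, FALSE = keep, NA = irreconcilable (non-palindromic pairs).
align_alleles <- function(ea_e, oa_e, ea_o, oa_o) {
  if (ea_o == ea_e && oa_o == oa_e) return(FALSE)
  if (ea_o == oa_e && oa_o == ea_e) return(TRUE)
  ca <- complement_allele(ea_o)
  cb <- complement_allele(oa_o)
  if (ca == ea_e && cb == oa_e) return(FALSE)
  if (ca == oa_e && cb == ea_e) return(TRUE)
  NA
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized instruments: %s on %s\n",
              attr(x, "exposure_id"), attr(x, "outcome_id")))
  print(table(x$action))
  invisible(x)
}
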