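#' Filter a summary dataset by association p-value
#'
#' Keeps records with `pval` strictly below the threshold (the
#' genome-wide instrument screen; the conventional relaxed threshold for
#' metabolite exposures is 1e-5). Input order is preserved.
#'
#' @param dataset a [summary_dataset].
#' @param p_threshold exclusive upper bound on the p-value, in (0, 1).
#' @return The filtered [summary_dataset].
#' @export
filter_by_pvalue <- function(dataset, p_threshold = 1e-5) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  keep_attrs(dataset, dataset$pval < p_threshold)
}

keep_attrs <- function(dataset, idx) {
  out <- as.data.frame(dataset)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_id = attr(dataset, "trait_id"),
            trait_type = attr(dataset, "trait_type"),
            class = class(dataset))
}

#' Greedy LD clumping of GWAS summary statistics
#'
#' Prunes correlated variants so retained instruments are approximately
#' independent: records are sorted by p-value (ties broken
#' lexicographically by SNP id, making the pass deterministic and
#' independent of input order); the best remaining SNP becomes an index
#' and removes every remaining SNP on the same chromosome within
#' `window_bp` base pairs (inclusive) whose r-squared with the index is at
#' least `r2_threshold`. Defaults are the conventional 500 kb window and
#' r-squared below 0.001.
#'
#' @param dataset a [summary_dataset]; every SNP must appear in `ld`.
#' @param ld an [ld_matrix] covering the dataset's SNPs.
#' @param window_bp half-width of the clumping window around the index
#'   SNP, in base pairs (boundary inclusive).
#' @param r2_threshold SNPs with r-squared at or above this value to a
#'   better index SNP are removed.
#' @return The retained records, in p-value order, with a `clump_log`
#'   attribute: a data frame mapping every input SNP to `kept` or to the
#'   index SNP responsible for its removal.
#' @export
clump <- function(dataset, ld, window_bp = 500000, r2_threshold = 0.001) {
  missing <- setdiff(dataset$snp, rownames(ld))
  if (length(missing)) {
    stop_mr("SNP(s) missing from LD matrix: ",
            paste(missing, collapse = ", "), class = "missing_ld_error")
  }
  ord <- order(dataset$pval, dataset$snp)
  df <- as.data.frame(dataset)[ord, , drop = FALSE]
  k <- nrow(df)
  removed_by <- rep(NA_character_, k)
  for (i in seq_len(k)) {
    if (!is.na(removed_by[i])) next
    later <- which(is.na(removed_by) & seq_len(k) > i)
    if (!length(later)) next
    hit <- df$chr[later] == df$chr[i] &
      abs(df$pos[later] - df$pos[i]) <= window_bp &
      ld[df$snp[later], df$snp[i]] >= r2_threshold
    removed_by[later[hit]] <- df$snp[i]
  }
  log <- data.frame(snp = df$snp,
                    disposition = ifelse(is.na(removed_by), "kept",
                                         paste0("dropped_clump:", removed_by)),
                    stringsAsFactors = FALSE)
  out <- keep_attrs(dataset, ord[is.na(removed_by)])
  attr(out, "clump_log") <- log
  out
}

#' Instrument-strength F-statistic
#'
#' The primary instrument-strength measure `F = (beta/se)^2`, the square
#' of the association z score, asymptotically equal to the single-SNP
#' regression F and requiring no allele frequency. When `eaf` and `n` are
#' supplied the variance explained `R2 = 2*eaf*(1-eaf)*beta^2` and the
#' alternative `F_r2 = R2*(n-2)/(1-R2)` are attached as attributes for
#' transparency.
#'
#' @param beta,se per-allele effect and its standard error (vectorized).
#' @param eaf,n optional effect-allele frequency and sample size.
#' @return Numeric vector of F statistics, with `r2` and `f_r2`
#'   attributes when computable.
#' @export
f_statistic <- function(beta, se, eaf = NULL, n = NULL) {
  f <- (beta / se)^2
  if (!is.null(eaf) && !is.null(n)) {
    r2 <- 2 * eaf * (1 - eaf) * beta^2
    attr(f, "r2") <- r2
    attr(f, "f_r2") <- r2 * (n - 2) / (1 - r2)
  }
  f
}

#' Select instrumental variables for an exposure
#'
#' The three-stage instrument screen: p-value filter (strict
#' `pval < p_threshold`), greedy LD [clump()]ing, then weak-instrument
#' removal (strict `F > f_threshold`). Every input SNP receives exactly
#' one disposition in the selection log: `kept`, `dropped_pval`,
#' `dropped_clump:<index snp>` or `dropped_weak`.
#'
#' @inheritParams clump
#' @inheritParams filter_by_pvalue
#' @param f_threshold exclusive lower bound on the F-statistic; the
#'   conventional weak-instrument floor is 10.
#' @return An object of class `instrument_set`: list with elements
#'   `trait_id`, `data` (kept records as a [summary_dataset]), `f_stats`
#'   (named vector over kept SNPs) and `selection_log`.
#' @export
select_instruments <- function(dataset, ld, p_threshold = 1e-5,
                               window_bp = 500000, r2_threshold = 0.001,
                               f_threshold = 10) {
  log <- data.frame(snp = dataset$snp, disposition = "dropped_pval",
                    f = f_statistic(dataset$beta, dataset$se),
                    stringsAsFactors = FALSE)
  sig <- filter_by_pvalue(dataset, p_threshold)
  clumped <- clump(sig, ld, window_bp, r2_threshold)
  clog <- attr(clumped, "clump_log")
  log$disposition[match(clog$snp, log$snp)] <- clog$disposition
  f <- f_statistic(clumped$beta, clumped$se, clumped$eaf, clumped$n)
  strong <- f > f_threshold
  kept_idx <- match(clumped$snp, log$snp)
  log$disposition[kept_idx[!strong]] <- "dropped_weak"
  kept <- keep_attrs(clumped, strong)
  attr(kept, "clump_log") <- NULL
  if (nrow(kept) == 0) {
    log_note <- "no instruments retained"
  } else {
    log_note <- NULL
  }
  structure(list(trait_id = attr(dataset, "trait_id"),
                 data = kept,
                 f_stats = stats::setNames(f[strong], clumped$snp[strong]),
                 selection_log = log,
                 note = log_note),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  tab <- table(sub(":.*$", "", x$selection_log$disposition))
  cat(sprintf("Instrument set for '%s': %d kept of %d candidate SNPs\n",
              x$trait_id %||% "?", nrow(x$data), nrow(x$selection_log)))
  print(tab)
  invisible(x)
}
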