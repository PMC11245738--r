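#' Hypergeometric pathway over-representation analysis
#'
#' For each pathway, tests whether the query metabolite set hits more
#' pathway members than expected under random draws from the annotation
#' universe: with universe size N, pathway size K and annotated query
#' size n, the p-value is the upper tail `P(X >= k_hits)` of
#' `Hypergeometric(N, K, n)`. Query members outside the universe are
#' dropped (the count is reported as an attribute). No multiple-testing
#' correction is applied by default; pathway analyses of this kind are
#' conventionally read at the relaxed level alpha = 0.10.
#'
#' @param query character vector of metabolite ids.
#' @param pathways a [pathway_collection].
#' @param alpha significance level for the `significant` flag.
#' @return Data frame (class `mr_enrichment`) sorted by p-value with
#'   columns `pathway_id`, `name`, `k_hits`, `m_pathway`, `n_query`,
#'   `n_universe`, `pval`, `significant`; attribute `n_dropped` counts
#'   query members outside the universe.
#' @export
ora_hypergeometric <- function(query, pathways, alpha = 0.10) {
  stopifnot(inherits(pathways, "pathway_collection"))
  query <- unique(query)
  annotated <- intersect(query, pathways$universe)
  n_dropped <- length(query) - length(annotated)
  if (length(annotated) == 0) {
    stop_mr("no query member is in the annotation universe",
            class = "empty_query_error")
  }
  n_universe <- length(pathways$universe)
  n_query <- length(annotated)
  rows <- lapply(names(pathways$pathways), function(id) {
    members <- pathways$pathways[[id]]
    k_hits <- length(intersect(annotated, members))
    m <- length(members)
    pval <- stats::phyper(k_hits - 1, m, n_universe - m, n_query,
                          lower.tail = FALSE)
    data.frame(pathway_id = id,
               name = unname(pathways$names[id]),
               k_hits = k_hits, m_pathway = m, n_query = n_query,
               n_universe = n_universe, pval = pval,
               significant = pval < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pval, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("mr_enrichment", "data.frame")
  out
}

#' Pathway enrichment of robust MR associations
#'
#' Takes the exposures classified as robust for one outcome and runs
#' [ora_hypergeometric()] against the pathway collection.
#'
#' @param decisions list of `mr_decision` objects for one outcome.
#' @param pathways a [pathway_collection].
#' @param alpha_pathway significance level for the pathway flag
#'   (default 0.10).
#' @param include_adjusted count `egger_preferred`/
#'   `heterogeneity_adjusted` calls with a significant primary p as
#'   robust, as in [overlap_robust()].
#' @return An `mr_enrichment` data frame; zero rows (with a warning)
#'   when no exposure is robust.
#' @export
enrich_significant <- function(decisions, pathways, alpha_pathway = 0.10,
                               include_adjusted = FALSE) {
  keep <- vapply(decisions, function(d) {
    d$classification == "robust_positive" ||
      (include_adjusted &&
         d$classification %in% c("egger_preferred",
                                 "heterogeneity_adjusted") &&
         isTRUE(d$evidence$primary_significant))
  }, logical(1))
  query <- unique(vapply(decisions[keep], `[[`, character(1), "exposure"))
  if (length(query) == 0) {
    warning("no robust exposures; empty enrichment result", call. = FALSE)
    out <- data.frame(pathway_id = character(), name = character(),
                      k_hits = integer(), m_pathway = integer(),
                      n_query = integer(), n_universe = integer(),
                      pval = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("mr_enrichment", "data.frame")
    return(out)
  }
  ora_hypergeometric(query, pathways, alpha = alpha_pathway)
}
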