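#' Construct a GWAS summary dataset
#'
#' A `summary_dataset` is a validated data frame of per-SNP association
#' records for a single trait: one row per variant with effect and other
#' alleles, per-allele effect estimate (per 1 SD of the trait for
#' continuous exposures, log odds for binary outcomes), its standard
#' error, p-value, effect-allele frequency and sample size.
#'
#' @param records data frame with columns `snp`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval` and optionally
#'   `eaf`, `n`, `ncase`, `ncontrol`.
#' @param trait_id identifier of the trait the records belong to.
#' @param trait_type `"continuous"` or `"binary"`.
#' @return An object of class `summary_dataset` (a data frame).
#' @export
summary_dataset <- function(records, trait_id,
                            trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  required <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                "beta", "se", "pval")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop_mr("missing mandatory column(s): ",
            paste(missing_cols, collapse = ", "), class = "format_error")
  }
  for (opt in c("eaf", "n", "ncase", "ncontrol")) {
    if (is.null(records[[opt]])) records[[opt]] <- NA_real_
  }
  records <- records[c(required, "eaf", "n", "ncase", "ncontrol")]
  dup <- records$snp[duplicated(records$snp)]
  if (length(dup)) {
    stop_mr("duplicate snp id(s): ", paste(unique(dup), collapse = ", "),
            class = "duplicate_snp_error")
  }
  bad <- validate_variant_rows(records)
  if (any(bad != "")) {
    stop_mr("invalid record(s): ",
            paste(utils::head(bad[bad != ""], 5), collapse = "; "),
            class = "invariant_error")
  }
  rownames(records) <- NULL
  structure(records,
            trait_id = trait_id, trait_type = trait_type,
            class = c("summary_dataset", "data.frame"))
}

# One diagnostic string per row; "" when the row satisfies every invariant.
validate_variant_rows <- function(df) {
  ok_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  msg <- character(nrow(df))
  add <- function(msg, bad, text) {
    ifelse(bad, ifelse(msg == "", text, paste(msg, text, sep = "; ")), msg)
  }
  msg <- add(msg, is.na(df$snp) | df$snp == "", "empty snp id")
  msg <- add(msg, !ok_allele(df$effect_allele) | !ok_allele(df$other_allele),
             "allele not a single A/C/G/T base")
  msg <- add(msg, ok_allele(df$effect_allele) & ok_allele(df$other_allele) &
               df$effect_allele == df$other_allele, "identical alleles")
  msg <- add(msg, !is.finite(df$pos) | df$pos < 1, "pos < 1")
  msg <- add(msg, !is.finite(df$beta), "non-numeric beta")
  msg <- add(msg, !is.finite(df$se) | df$se <= 0, "se not > 0")
  msg <- add(msg, !is.finite(df$pval) | df$pval <= 0 | df$pval > 1,
             "pval outside (0, 1]")
  msg <- add(msg, !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1),
             "eaf outside (0, 1)")
  msg <- add(msg, !is.na(df$n) & df$n <= 0, "n not > 0")
  msg
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a TSV (optionally gzip-compressed) of per-SNP summary statistics,
#' validates every row against the record invariants (positive SE, p-value
#' in (0, 1], single-base alleles, frequency in (0, 1)) and returns the
#' valid rows as a [summary_dataset]. Invalid rows are dropped with a
#' warning carrying row-level diagnostics; a duplicated SNP id is an error.
#'
#' @param path path to the file. Mandatory columns (under the default
#'   mapping): `snp`, `chr`, `pos`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pval`; `eaf`, `n`, `ncase`, `ncontrol` are optional.
#' @param trait_id,trait_type passed to [summary_dataset()].
#' @param columns named list mapping the canonical column names above to
#'   the names used in the file, e.g. `list(snp = "rsid", pval = "p")`.
#'   Public summary-statistics files disagree on headers; no auto-sniffing
#'   beyond this mapping is attempted.
#' @return A [summary_dataset]. The number of rejected rows is available
#'   as `attr(x, "n_rejected")`.
#' @export
read_sumstats <- function(path, trait_id,
                          trait_type = c("continuous", "binary"),
                          columns = list()) {
  trait_type <- match.arg(trait_type)
  canonical <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n", "ncase", "ncontrol")
  mapping <- stats::setNames(as.list(canonical), canonical)
  mapping[names(columns)] <- columns
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  mandatory <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                 "beta", "se", "pval")
  missing_cols <- mandatory[!vapply(mandatory, function(k)
    mapping[[k]] %in% names(raw), logical(1))]
  if (length(missing_cols)) {
    stop_mr("missing mandatory column(s): ",
            paste(unlist(mapping[missing_cols]), collapse = ", "),
            class = "format_error")
  }
  df <- data.frame(snp = raw[[mapping$snp]],
                   chr = raw[[mapping$chr]],
                   stringsAsFactors = FALSE)
  num <- function(key) {
    col <- mapping[[key]]
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    suppressWarnings(as.numeric(raw[[col]]))
  }
  df$pos <- num("pos")
  df$effect_allele <- toupper(raw[[mapping$effect_allele]])
  df$other_allele <- toupper(raw[[mapping$other_allele]])
  for (key in c("eaf", "beta", "se", "pval", "n", "ncase", "ncontrol")) {
    df[[key]] <- num(key)
  }
  diagnostics <- validate_variant_rows(df)
  bad <- diagnostics != ""
  if (any(bad)) {
    warning(sprintf("%d row(s) rejected: %s", sum(bad),
                    paste(sprintf("row %d (%s)", which(bad)[seq_len(min(5, sum(bad)))],
                                  diagnostics[bad][seq_len(min(5, sum(bad)))]),
                          collapse = "; ")),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  out <- summary_dataset(df, trait_id = trait_id, trait_type = trait_type)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("GWAS summary dataset '%s' (%s trait): %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a square LD (r-squared) matrix
#'
#' The file must be a square tab-delimited table whose header row and
#' first column list the same SNP ids in the same order. Entries are
#' pairwise r-squared values; the matrix must be symmetric (tolerance
#' 1e-8), have unit diagonal, and lie in \[0, 1\].
#'
#' @param path path to the TSV file.
#' @return An object of class `ld_matrix`: the numeric r-squared matrix
#'   with SNP ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  ld_matrix(m, ids)
}

#' Construct/validate an LD matrix object
#'
#' @param r2 square numeric matrix of pairwise r-squared values.
#' @param snp_ids SNP ids in matrix order; defaults to `rownames(r2)`.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  if (is.null(snp_ids)) stop_mr("LD matrix needs snp ids", class = "format_error")
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(snp_ids)) {
    stop_mr("LD matrix is not square over its snp ids", class = "format_error")
  }
  if (!is.null(colnames(r2)) && !identical(colnames(r2), as.character(snp_ids))) {
    stop_mr("LD header and first column disagree on snp order",
            class = "format_error")
  }
  dimnames(r2) <- list(snp_ids, snp_ids)
  asym <- abs(r2 - t(r2))
  if (any(asym > 1e-8)) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop_mr(sprintf("LD matrix not symmetric: (%s, %s) = %g vs %g",
                    snp_ids[idx[1]], snp_ids[idx[2]],
                    r2[idx[1], idx[2]], r2[idx[2], idx[1]]),
            class = "symmetry_error")
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    stop_mr("LD matrix diagonal must equal 1", class = "range_error")
  }
  if (any(r2 < 0 | r2 > 1)) {
    stop_mr("LD entries must lie in [0, 1]", class = "range_error")
  }
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Read pathway sets in GMT format
#'
#' One pathway per line, tab separated: id, description, then member
#' metabolite ids. Duplicate members within a line are collapsed. The
#' universe of annotatable metabolites defaults to the union of all
#' members unless supplied.
#'
#' @param path path to the GMT file.
#' @param universe optional character vector of metabolite ids defining
#'   the annotation universe; must contain every pathway member.
#' @return An object of class `pathway_collection`: a list with elements
#'   `pathways` (named list of member vectors), `names` (named character
#'   vector of descriptions) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) {
    stop_mr("GMT line ", which(short)[1], " has fewer than 3 fields",
            class = "format_error")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  descs <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  pathway_collection(stats::setNames(members, ids),
                     stats::setNames(descs, ids), universe)
}

#' @rdname read_gmt
#' @param pathways named list of pathway member vectors.
#' @param names named character vector of pathway descriptions.
#' @export
pathway_collection <- function(pathways, names = NULL, universe = NULL) {
  if (any(vapply(pathways, length, integer(1)) == 0L)) {
    stop_mr("pathway with empty member set", class = "format_error")
  }
  all_members <- unique(unlist(pathways, use.names = FALSE))
  if (is.null(universe)) {
    universe <- all_members
  } else if (length(setdiff(all_members, universe))) {
    stop_mr("pathway members outside the supplied universe",
            class = "format_error")
  }
  structure(list(pathways = pathways,
                 names = names %||% stats::setNames(base::names(pathways),
                                                    base::names(pathways)),
                 universe = universe),
            class = "pathway_collection")
}

#' Write MR results to a tab-delimited table
#'
#' Columns: exposure, outcome, method, nsnp, beta, se, pval, or, ci_low,
#' ci_high. Odds-ratio columns are formatted to 3 decimals as in the
#' standard per-method results tables; beta/se/pval keep full precision so
#' a written table can be re-read losslessly.
#'
#' @param results an [mr_fit] object, a data frame of results rows, or a
#'   list of `mr_result` objects.
#' @param path output file path.
#' @export
write_mr_results <- function(results, path) {
  df <- as_mr_result_table(results)
  for (col in c("or", "ci_low", "ci_high")) {
    df[[col]] <- formatC(df[[col]], digits = 3, format = "f")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_mr_result_table <- function(results) {
  cols <- c("exposure", "outcome", "method", "nsnp", "beta", "se", "pval",
            "or", "ci_low", "ci_high")
  if (inherits(results, "mr_fit")) return(results$results[cols])
  if (is.data.frame(results)) {
    if (nrow(results) == 0) {
      return(stats::setNames(
        data.frame(matrix(nrow = 0, ncol = length(cols))), cols))
    }
    return(results[cols])
  }
  if (length(results) == 0) {
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(cols))), cols))
  }
  do.call(rbind, lapply(results, function(r) as.data.frame(unclass(r)[cols])))
}
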