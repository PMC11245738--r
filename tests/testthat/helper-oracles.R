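# Independent reference implementations used as oracles, deliberately
# routed through different code paths (lm / explicit combinatorics /
# naive loops) than the package internals they check.

# Fixed-effects IVW via lm through the origin; base (unit-sigma) SE.
oracle_ivw <- function(be, bo, so) {
  fit <- stats::lm(bo ~ 0 + be, weights = 1 / so^2)
  s <- summary(fit)
  list(beta = unname(coef(fit)[1]),
       se_fe = unname(s$coefficients[1, 2] / s$sigma))
}

# Egger WLS with intercept via lm; base SEs.
oracle_egger <- function(be, bo, so) {
  flip <- be < 0
  bo[flip] <- -bo[flip]
  be[flip] <- -be[flip]
  fit <- stats::lm(bo ~ be, weights = 1 / so^2)
  s <- summary(fit)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_intercept = unname(s$coefficients[1, 2] / s$sigma),
       se_slope = unname(s$coefficients[2, 2] / s$sigma))
}

# Naive greedy clumping: repeatedly pick the smallest-p remaining SNP
# (lexicographic tie-break) and delete its window/LD neighbours.
oracle_clump <- function(df, r2, window_bp, r2_threshold) {
  kept <- character()
  remaining <- df
  while (nrow(remaining)) {
    best <- remaining[order(remaining$pval, remaining$snp)[1], ]
    kept <- c(kept, best$snp)
    drop <- remaining$chr == best$chr &
      abs(remaining$pos - best$pos) <= window_bp &
      r2[remaining$snp, best$snp] >= r2_threshold
    drop[remaining$snp == best$snp] <- TRUE
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

# Exhaustive hypergeometric upper tail via binomial coefficients.
oracle_hyper_tail <- function(k_hits, m, n_universe, n_query) {
  x <- k_hits:min(m, n_query)
  sum(choose(m, x) * choose(n_universe - m, n_query - x)) /
    choose(n_universe, n_query)
}

# Harmonized set straight from a simulated study (no p-value selection),
# for estimator-level Monte Carlo work.
harmonize_study <- function(study, ...) {
  harmonize_pair(study$exposure, study$outcome, ...)
}

# Quick builder for hand-crafted harmonized fixtures.
hset <- function(be, se_e, bo, se_o, ...) {
  harmonized_set(snp = sprintf("s%d", seq_along(be)),
                 beta_exp = be, se_exp = se_e,
                 beta_out = bo, se_out = se_o, ...)
}

# Minimal valid sumstats data frame.
sumstats_df <- function(n = 3, snp = sprintf("rs%d", seq_len(n))) {
  data.frame(snp = snp, chr = "1", pos = seq_len(n) * 1e6,
             effect_allele = "A", other_allele = "G", eaf = 0.3,
             beta = 0.1, se = 0.01, pval = 1e-8, n = 10000,
             stringsAsFactors = FALSE)
}

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
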