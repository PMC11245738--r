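#' Configuration for a simulated two-sample MR study
#'
#' Defines the structural model behind a pair of exposure/outcome GWAS
#' summary datasets with known ground truth. Per SNP j, the true effect on
#' the exposure (per 1 SD) is \eqn{\gamma_j \sim N(0, \code{gamma_sd}^2)}.
#' With probability `pleiotropy_prob` the SNP carries a direct (pleiotropic)
#' effect \eqn{\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)}, defined on the
#' exposure-increasing allele (allele labels are arbitrary, so a directional
#' pleiotropy only has meaning relative to that orientation);
#' `inside_violation` adds a component proportional to the instrument
#' strength \eqn{|\gamma_j|}, breaking the InSIDE assumption when non-zero.
#' The true outcome effect is
#' \eqn{\Gamma_j = \beta\,\gamma_j + \mathrm{sign}(\gamma_j)\,\alpha_j}.
#' Standard errors follow the first-order formula for a standardized trait,
#' \eqn{\sigma = 1/\sqrt{2\,p(1-p)\,n}} with effect-allele frequency p, and
#' observed effects are drawn as \eqn{N(\mathrm{true}, \sigma^2)}.
#'
#' Defaults mirror a metabolite-on-osteoarthritis study: an exposure GWAS
#' of n = 8,299 (a population-cohort metabolite panel) and a binary outcome
#' GWAS of n = 462,933 with a roughly 1:9 case:control split, per-1-SD
#' exposure effects with SD 0.2 among selected instruments (mean F around
#' 140), and a realistic minority of palindromic (A/T or C/G) variants.
#'
#' @param n_snps number of candidate instruments to generate.
#' @param beta_causal true causal effect of the exposure on the outcome
#'   (log odds per 1 SD when `outcome_binary`).
#' @param n_exposure,n_outcome GWAS sample sizes on each side.
#' @param maf_range range of the uniform minor-allele-frequency draw,
#'   a sub-interval of (0, 0.5].
#' @param gamma_sd SD of true SNP-to-exposure effects (per-allele, per 1 SD).
#' @param pleiotropy_prob probability a SNP carries a direct effect.
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of direct effects.
#' @param inside_violation coefficient coupling direct effects to
#'   instrument strength; 0 preserves InSIDE.
#' @param ld_block_size number of consecutive SNPs per LD block.
#' @param ld_within_r2 r-squared between distinct SNPs in a block.
#' @param palindromic_fraction expected fraction of A/T or C/G variants.
#' @param outcome_binary if `TRUE` the outcome dataset is labelled binary
#'   with effects on the log-odds scale and a 1:9 case:control split.
#' @param seed integer seed making the study reproducible.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_study()]
#' @export
sim_config <- function(n_snps = 50, beta_causal = 0,
                       n_exposure = 8299, n_outcome = 462933,
                       maf_range = c(0.05, 0.5), gamma_sd = 0.2,
                       pleiotropy_prob = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0.02, inside_violation = 0,
                       ld_block_size = 1, ld_within_r2 = 0,
                       palindromic_fraction = 0.15,
                       outcome_binary = TRUE, seed = 1L) {
  stopifnot(is_scalar_number(n_snps), n_snps >= 1,
            is_scalar_number(beta_causal),
            is_scalar_number(n_exposure), n_exposure > 0,
            is_scalar_number(n_outcome), n_outcome > 0,
            length(maf_range) == 2, all(maf_range > 0), all(maf_range <= 0.5),
            maf_range[1] <= maf_range[2],
            is_scalar_number(gamma_sd), gamma_sd > 0,
            is_scalar_number(pleiotropy_prob),
            pleiotropy_prob >= 0, pleiotropy_prob <= 1,
            is_scalar_number(pleiotropy_mean),
            is_scalar_number(pleiotropy_sd), pleiotropy_sd >= 0,
            is_scalar_number(inside_violation),
            is_scalar_number(ld_block_size), ld_block_size >= 1,
            is_scalar_number(ld_within_r2),
            ld_within_r2 >= 0, ld_within_r2 < 1,
            is_scalar_number(palindromic_fraction),
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            is.logical(outcome_binary), length(outcome_binary) == 1,
            is_scalar_number(seed))
  structure(list(n_snps = as.integer(n_snps), beta_causal = beta_causal,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 maf_range = maf_range, gamma_sd = gamma_sd,
                 pleiotropy_prob = pleiotropy_prob,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 inside_violation = inside_violation,
                 ld_block_size = as.integer(ld_block_size),
                 ld_within_r2 = ld_within_r2,
                 palindromic_fraction = palindromic_fraction,
                 outcome_binary = outcome_binary, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Draws one study from the structural model in [sim_config()]:
#' exposure and outcome [summary_dataset]s over the same SNPs, a
#' block-diagonal [ld_matrix] (constant `ld_within_r2` within blocks,
#' zero between), and a `truth` record carrying the causal effect, the
#' per-SNP \eqn{\gamma_j} and \eqn{\alpha_j}, and outlier flags. Output is
#' deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return An object of class `simulated_study`: a list with elements
#'   `exposure`, `outcome`, `ld`, `truth` and `config`.
#' @examples
#' study <- simulate_study(sim_config(n_snps = 20, beta_causal = 0.1, seed = 3))
#' nrow(study$exposure)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$n_snps
  snp <- sprintf("rs%05d", seq_len(k))

  maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
  gamma <- stats::rnorm(k, 0, config$gamma_sd)
  pleio <- stats::runif(k) < config$pleiotropy_prob
  alpha <- ifelse(pleio,
                  stats::rnorm(k, config$pleiotropy_mean, config$pleiotropy_sd) +
                    config$inside_violation * abs(gamma),
                  0)
  sgn <- ifelse(gamma >= 0, 1, -1)
  big_gamma <- config$beta_causal * gamma + sgn * alpha

  se_exp <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
  se_out <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)
  beta_exp <- stats::rnorm(k, gamma, se_exp)
  beta_out <- stats::rnorm(k, big_gamma, se_out)

  # alleles: palindromic SNPs get A/T or C/G pairs, others a mixed pair
  pal <- stats::runif(k) < config$palindromic_fraction
  pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                      ncol = 2, byrow = TRUE)
  npal_pairs <- matrix(c("A", "G", "G", "A", "A", "C", "C", "A",
                         "T", "G", "G", "T", "T", "C", "C", "T"),
                       ncol = 2, byrow = TRUE)
  pick <- ifelse(pal, sample.int(4, k, replace = TRUE),
                 sample.int(8, k, replace = TRUE))
  ea <- ifelse(pal, pal_pairs[pmin(pick, 4), 1], npal_pairs[pick, 1])
  oa <- ifelse(pal, pal_pairs[pmin(pick, 4), 2], npal_pairs[pick, 2])

  # genome layout: ld_block_size consecutive SNPs per block, blocks spaced
  # far beyond any clumping window; 10 kb between SNPs within a block
  block <- (seq_len(k) - 1L) %/% config$ld_block_size
  within <- (seq_len(k) - 1L) %% config$ld_block_size
  chrom <- as.character(block %% 22 + 1L)
  pos <- 1e6 + (block %/% 22) * 1e7 + within * 1e4

  r2 <- (outer(block, block, "==") - diag(k)) * config$ld_within_r2 + diag(k)
  dimnames(r2) <- list(snp, snp)

  mk <- function(beta, se, trait_id, trait_type, n, ncase, ncontrol) {
    summary_dataset(data.frame(
      snp = snp, chr = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = maf,
      beta = beta, se = se,
      # two-sided normal p, floored at the smallest positive double so
      # extreme associations keep a representable p in (0, 1]
      pval = pmax(p_from_z(beta / se), .Machine$double.xmin),
      n = n, ncase = ncase, ncontrol = ncontrol,
      stringsAsFactors = FALSE), trait_id, trait_type)
  }
  ncase <- if (config$outcome_binary) round(config$n_outcome / 10) else NA_real_
  structure(list(
    exposure = mk(beta_exp, se_exp, "sim_exposure", "continuous",
                  config$n_exposure, NA_real_, NA_real_),
    outcome = mk(beta_out, se_out, "sim_outcome",
                 if (config$outcome_binary) "binary" else "continuous",
                 config$n_outcome, ncase,
                 if (config$outcome_binary) config$n_outcome - ncase else NA_real_),
    ld = ld_matrix(r2),
    truth = list(beta_causal = config$beta_causal, gamma = gamma,
                 alpha = alpha, outlier = stats::setNames(logical(k), snp)),
    config = config), class = "simulated_study")
}

#' Spike outlier SNPs into a simulated study
#'
#' Adds `shift` to the outcome effect of each named SNP (and updates its
#' p-value and the truth outlier flags), leaving everything else
#' untouched. Used to plant known pleiotropic outliers for testing
#' outlier-detection machinery.
#'
#' @param study a [simulate_study()] result.
#' @param snps SNP ids (or integer indices) to shift.
#' @param shift amount added to the outcome beta of each named SNP.
#' @return The modified `simulated_study`.
#' @export
spike_outliers <- function(study, snps, shift) {
  stopifnot(inherits(study, "simulated_study"), is_scalar_number(shift))
  if (is.numeric(snps)) snps <- study$outcome$snp[snps]
  idx <- match(snps, study$outcome$snp)
  if (anyNA(idx)) {
    stop_mr("unknown snp id(s): ", paste(snps[is.na(idx)], collapse = ", "),
            class = "unknown_snp_error")
  }
  study$outcome$beta[idx] <- study$outcome$beta[idx] + shift
  study$outcome$pval[idx] <-
    pmax(p_from_z(study$outcome$beta[idx] / study$outcome$se[idx]),
         .Machine$double.xmin)
  study$truth$outlier[idx] <- TRUE
  study
}

#' Simulate a batch of independent null studies
#'
#' Generates `n_reps` studies under the null (`beta_causal` must be 0),
#' each with a distinct sub-seed derived from the master seed by the
#' counter scheme `(seed + 7919 * rep) mod (2^31 - 1)`, recorded in each
#' study's config so any replicate can be regenerated in isolation.
#'
#' @param config a [sim_config()] with `beta_causal = 0`.
#' @param n_reps number of replicate studies.
#' @return List of `simulated_study` objects (empty when `n_reps = 0`).
#' @export
simulate_null_batch <- function(config, n_reps) {
  stopifnot(inherits(config, "sim_config"),
            is_scalar_number(n_reps), n_reps >= 0)
  if (config$beta_causal != 0) {
    stop_mr("null batch requires beta_causal = 0", class = "config_error")
  }
  lapply(seq_len(n_reps), function(i) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + 7919 * i) %% 2147483647)
    simulate_study(cfg)
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(paste0("Simulated two-sample MR study: %d SNPs, true beta = %g",
                     ", %d pleiotropic, %d spiked outlier(s), seed %d\n"),
              x$config$n_snps, x$truth$beta_causal, sum(x$truth$alpha != 0),
              sum(x$truth$outlier), x$config$seed))
  invisible(x)
}
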