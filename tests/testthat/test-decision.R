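stub_result <- function(method, beta, pval, nsnp = 10) {
  h <- hset(1, 0.01, beta, abs(beta) / 2 + 0.01)
  r <- mr_wald_ratio(h)
  r$method <- method
  r$beta <- beta
  r$pval <- pval
  r$nsnp <- nsnp
  r$exposure <- "met1"
  r$outcome <- "oa"
  r
}

stub_report <- function(q_p = 0.4, int_p = 0.6, steiger = TRUE,
                        presso_p = 0.5) {
  structure(list(
    q_ivw = c(q = 1, df = 9, pval = q_p),
    q_egger = c(q = 1, df = 8, pval = q_p),
    egger_intercept = c(intercept = 0.001, se = 0.01, pval = int_p),
    presso = structure(list(global_pval = presso_p, outliers = character()),
                       class = "mr_presso"),
    loo = structure(data.frame(snp = "s1", beta = 1, se = 1, pval = 0.01),
                    all_significant = TRUE),
    steiger = list(r2_exp = 0.5, r2_out = 0.01, direction = steiger,
                   pval = 1e-5),
    skipped = character()), class = "mr_sensitivity")
}

test_that("classification follows the decision rules in order", {
  ivw <- stub_result("ivw_re", 0.11, 0.013)
  egg <- stub_result("egger", 0.06, 0.654)
  wm <- stub_result("weighted_median", 0.14, 0.019)

  # clean, significant, direction-consistent: robust even though the
  # supplementary estimators are non-significant
  d <- classify_association(ivw, egg, wm, stub_report())
  expect_equal(d$classification, "robust_positive")
  expect_true(d$evidence$ivw_significant)

  # pleiotropy without heterogeneity prefers Egger
  d <- classify_association(ivw, egg, wm, stub_report(int_p = 0.01, q_p = 0.2))
  expect_equal(d$classification, "egger_preferred")
  expect_equal(d$primary$method, "egger")

  # heterogeneity without pleiotropy keeps random-effects IVW
  d <- classify_association(ivw, egg, wm, stub_report(q_p = 0.01, int_p = 0.3))
  expect_equal(d$classification, "heterogeneity_adjusted")
  expect_equal(d$primary$method, "ivw_re")

  # failed Steiger direction dominates everything else
  d <- classify_association(ivw, egg, wm, stub_report(steiger = FALSE))
  expect_equal(d$classification, "direction_failed")

  # inconsistent directions block the robust call
  wm_neg <- stub_result("weighted_median", -0.02, 0.6)
  d <- classify_association(ivw, egg, wm_neg, stub_report())
  expect_equal(d$classification, "not_significant")

  # missing estimators mean too few instruments
  d <- classify_association(ivw, NULL, NULL, stub_report())
  expect_equal(d$classification, "insufficient_instruments")
})

test_that("the PRESSO global test joins the pleiotropy verdict only under policy", {
  ivw <- stub_result("ivw_re", 0.11, 0.013)
  egg <- stub_result("egger", 0.09, 0.04)
  wm <- stub_result("weighted_median", 0.12, 0.02)
  rep <- stub_report(int_p = 0.5, presso_p = 0.01)
  expect_equal(classify_association(ivw, egg, wm, rep)$classification,
               "robust_positive")
  expect_equal(classify_association(ivw, egg, wm, rep,
                                    policy = "egger_or_presso")$classification,
               "egger_preferred")
})

test_that("classification is a pure function of the stored evidence", {
  set.seed(8)
  for (i in 1:20) {
    rep <- stub_report(q_p = runif(1), int_p = runif(1),
                       steiger = runif(1) > 0.2)
    ivw <- stub_result("ivw_re", rnorm(1, 0.1, 0.05), runif(1))
    egg <- stub_result("egger", rnorm(1, 0.1, 0.05), runif(1))
    wm <- stub_result("weighted_median", rnorm(1, 0.1, 0.05), runif(1))
    d1 <- classify_association(ivw, egg, wm, rep)
    d2 <- classify_association(ivw, egg, wm, rep)
    expect_identical(d1$classification, d2$classification)
    expect_identical(d1$evidence, d2$evidence)
  }
})

test_that("run_full_analysis recovers a clean simulated effect end to end", {
  study <- simulate_study(sim_config(n_snps = 40, beta_causal = 0.1,
                                     seed = 404))
  res <- run_full_analysis(study$exposure, study$outcome, study$ld,
                           n_boot = 100, presso_n_sim = 300, seed = 5)
  expect_s3_class(res, "mr_analysis")
  expect_true(res$decision$classification %in%
                c("robust_positive", "heterogeneity_adjusted"))
  expect_equal(res$fit_final$details$ivw$beta, 0.1, tolerance = 0.05)
  expect_equal(res$log$n_input, 40)

  # no instruments below the p threshold: insufficient
  weak <- simulate_study(sim_config(n_snps = 10, gamma_sd = 1e-4,
                                    beta_causal = 0, seed = 2))
  res2 <- run_full_analysis(weak$exposure, weak$outcome, weak$ld,
                            n_boot = 50, presso_n_sim = 100, seed = 5)
  expect_equal(res2$decision$classification, "insufficient_instruments")
})

test_that("a spiked outlier is excluded once and logged", {
  base <- simulate_study(sim_config(n_snps = 25, beta_causal = 0.1,
                                    palindromic_fraction = 0, seed = 77))
  # spike a SNP that survives instrument selection
  target <- select_instruments(base$exposure, base$ld)$data$snp[1]
  shift <- 10 * base$outcome$se[match(target, base$outcome$snp)]
  spiked <- spike_outliers(base, target, shift = shift)
  res <- run_full_analysis(spiked$exposure, spiked$outcome, spiked$ld,
                           n_boot = 100, presso_n_sim = 500, seed = 9)
  expect_true(target %in% res$log$presso_excluded)
  expect_equal(res$log$n_final, res$log$n_harmonized -
                 length(res$log$presso_excluded))
  expect_lt(abs(res$fit_final$details$ivw$beta - 0.1),
            abs(res$fit$details$ivw$beta - 0.1))
})

test_that("file-path inputs run the same pipeline", {
  study <- simulate_study(sim_config(n_snps = 15, beta_causal = 0.1,
                                     seed = 55))
  exp_path <- write_sumstats_file(as.data.frame(study$exposure))
  out_path <- write_sumstats_file(as.data.frame(study$outcome))
  ld_path <- tempfile(fileext = ".tsv")
  write.table(data.frame(snp = rownames(study$ld), unclass(study$ld),
                         check.names = FALSE),
              ld_path, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- run_full_analysis(exp_path, out_path, ld_path,
                           n_boot = 50, presso_n_sim = 100, seed = 3)
  obj <- run_full_analysis(study$exposure, study$outcome, study$ld,
                           n_boot = 50, presso_n_sim = 100, seed = 3)
  expect_equal(res$fit_final$results$beta, obj$fit_final$results$beta,
               tolerance = 1e-9)
})

test_that("null end-to-end analyses are rarely called robust, monotonically in alpha", {
  cfg <- sim_config(n_snps = 30, beta_causal = 0, palindromic_fraction = 0,
                    seed = 2024)
  studies <- simulate_null_batch(cfg, 300)
  calls <- vapply(seq_along(studies), function(i) {
    s <- studies[[i]]
    h <- harmonize_pair(s$exposure, s$outcome)
    fit <- mr_fit(h, n_boot = 50, seed = i)
    rep <- mr_sensitivity(h, n_sim = 300, seed = i)
    d05 <- classify_association(fit$details$ivw, fit$details$egger,
                                fit$details$weighted_median, rep,
                                alpha = 0.05)
    d01 <- classify_association(fit$details$ivw, fit$details$egger,
                                fit$details$weighted_median, rep,
                                alpha = 0.01)
    c(d05$classification == "robust_positive",
      d01$classification == "robust_positive",
      d05$evidence$pleiotropy == d01$evidence$pleiotropy &&
        d05$evidence$heterogeneity == d01$evidence$heterogeneity)
  }, logical(3))
  expect_lte(mean(calls[1, ]), 0.08)
  # tightening alpha never adds a replicate to the robust set, as long as
  # the heterogeneity/pleiotropy verdicts themselves do not flip (when a
  # borderline intercept p crosses alpha the classification can jump
  # between branches in either direction)
  stable <- calls[3, ]
  expect_true(all(calls[1, stable] | !calls[2, stable]))
})

test_that("robust overlap intersects outcomes with direction agreement", {
  mk <- function(exposure, beta = 0.1, class = "robust_positive") {
    structure(list(exposure = exposure, outcome = "o",
                   classification = class,
                   primary = list(beta = beta, pval = 0.01),
                   evidence = list(primary_significant = TRUE)),
              class = "mr_decision")
  }
  decisions <- list(
    oa = list(mk("m1"), mk("m2")),
    hip = list(mk("m2")),
    knee = list(mk("m2"), mk("m3")))
  ov <- overlap_robust(decisions)
  expect_equal(ov$intersection, "m2")

  # one empty outcome empties the intersection
  decisions$hip <- list(mk("m9", class = "not_significant"))
  expect_length(overlap_robust(decisions)$intersection, 0)

  # a sign flip in one outcome excludes the exposure
  decisions$hip <- list(mk("m2", beta = -0.1))
  expect_length(overlap_robust(decisions)$intersection, 0)

  expect_error(overlap_robust(decisions["oa"]), class = "config_error")

  # adjusted classifications count only when asked for
  decisions$hip <- list(mk("m2", class = "heterogeneity_adjusted"))
  expect_length(overlap_robust(decisions)$intersection, 0)
  expect_equal(overlap_robust(decisions, include_adjusted = TRUE)$intersection,
               "m2")
})
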