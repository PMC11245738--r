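test_that("Wald ratio divides effects and propagates the outcome SE", {
  h <- hset(0.2, 0.01, 0.02, 0.01)
  r <- mr_wald_ratio(h)
  expect_equal(r$beta, 0.1)
  expect_equal(r$se, 0.05)

  r0 <- mr_wald_ratio(hset(0.2, 0.01, 0, 0.01))
  expect_equal(r0$beta, 0)
  expect_equal(r0$pval, 1)

  expect_error(mr_wald_ratio(hset(0, 0.01, 0.02, 0.01)),
               class = "undefined_ratio_error")
})

test_that("IVW reduces to the Wald ratio with one SNP and to the mean with equal weights", {
  h1 <- hset(0.2, 0.01, 0.02, 0.01)
  expect_equal(mr_ivw(h1)$beta, mr_wald_ratio(h1)$beta)
  expect_equal(mr_ivw(h1)$se, mr_wald_ratio(h1)$se)

  h3 <- hset(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.3), 0.05)
  expect_equal(mr_ivw(h3)$beta, 0.2)
})

test_that("IVW and Egger match the lm weighted-least-squares oracle", {
  set.seed(1)
  for (i in 1:50) {
    k <- sample(3:20, 1)
    be <- rnorm(k, 0.2, 0.1)
    bo <- rnorm(k, 0.02, 0.02)
    so <- runif(k, 0.005, 0.05)
    h <- hset(be, 0.01, bo, so)
    oi <- oracle_ivw(kept_rows(h)$beta_exp, kept_rows(h)$beta_out,
                     kept_rows(h)$se_out)
    ivw <- mr_ivw(h, "fixed")
    expect_equal(ivw$beta, oi$beta, tolerance = 1e-10)
    expect_equal(ivw$se, oi$se_fe, tolerance = 1e-10)
    oe <- oracle_egger(be, bo, so)
    egg <- mr_egger(h)
    expect_equal(egg$beta, oe$slope, tolerance = 1e-10)
    expect_equal(egg$extras$intercept, oe$intercept, tolerance = 1e-10)
  }
})

test_that("random-effects scaling never deflates the IVW SE", {
  h <- hset(c(1, 1, 1, 1), 0.01, c(0.1, 0.1, 0.1, 0.1), 0.05)
  expect_equal(mr_ivw(h, "random")$se, mr_ivw(h, "fixed")$se)
  h2 <- hset(c(1, 1, 1, 1), 0.01, c(0.0, 0.1, 0.2, 0.4), 0.05)
  expect_gt(mr_ivw(h2, "random")$se, mr_ivw(h2, "fixed")$se)
})

test_that("Egger recovers an exact linear relation and needs 3 SNPs", {
  be <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  h <- hset(be, 0.01, 0.05 + 0.3 * be, 0.02)
  egg <- mr_egger(h)
  expect_equal(egg$beta, 0.3, tolerance = 1e-12)
  expect_equal(egg$extras$intercept, 0.05, tolerance = 1e-12)
  expect_equal(egg$extras$q, 0, tolerance = 1e-20)
  expect_error(mr_egger(hset(c(0.1, 0.2), 0.01, c(0.1, 0.2), 0.02)),
               class = "insufficient_snps_error")
})

test_that("weighted median interpolates the weighted 50th percentile", {
  h <- hset(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.9), 0.05)
  expect_equal(mr_weighted_median(h, n_boot = 0)$beta, 0.2)
  expect_error(mr_weighted_median(hset(c(1, 1), 0.01, c(1, 1), 0.05),
                                  n_boot = 0),
               class = "insufficient_snps_error")
  # majority-valid breakdown: 10 instruments at ratio 0.1 vs 40% invalid
  # weight at ratio 5 leaves the estimate at the valid cluster
  set.seed(77)
  be <- rep(1, 16)
  bo <- c(rnorm(10, 0.1, 0.01), rnorm(6, 5, 0.01))
  so <- c(rep(0.05, 10), rep(0.0498, 6))  # invalid weight just under 40%
  est <- mr_weighted_median(hset(be, 0.001, bo, so), n_boot = 0)$beta
  expect_gt(est, 0.08)
  expect_lt(est, 0.12)
})

test_that("weighted median and mode bootstrap SEs are seeded and reproducible", {
  study <- simulate_study(sim_config(n_snps = 25, beta_causal = 0.1, seed = 3))
  h <- harmonize_study(study)
  m1 <- mr_weighted_median(h, n_boot = 200, seed = 42)
  m2 <- mr_weighted_median(h, n_boot = 200, seed = 42)
  expect_identical(m1$se, m2$se)
  expect_gt(m1$se, 0)
  w1 <- mr_weighted_mode(h, n_boot = 100, seed = 42)
  w2 <- mr_weighted_mode(h, n_boot = 100, seed = 42)
  expect_identical(w1$se, w2$se)
})

test_that("weighted mode finds the dominant ratio cluster", {
  h0 <- hset(rep(1, 5), 0.01, rep(0.2, 5), 0.05)
  expect_equal(mr_weighted_mode(h0, n_boot = 0)$beta, 0.2)

  set.seed(5)
  bo <- c(rnorm(7, 0.1, 0.005), rnorm(3, 0.9, 0.005))
  h <- hset(rep(1, 10), 0.01, bo, 0.05)
  est <- mr_weighted_mode(h, n_boot = 0)$beta
  expect_gt(est, 0.05)
  expect_lt(est, 0.15)
  # permutation invariance
  perm <- sample(10)
  hp <- hset(rep(1, 10), 0.01, bo[perm], 0.05)
  expect_equal(mr_weighted_mode(hp, n_boot = 0)$beta, est, tolerance = 1e-12)
})

test_that("odds-ratio presentation exponentiates with 1.96 bounds", {
  ci <- to_odds_ratio(0, 0.1)
  expect_equal(unname(ci), c(1, exp(-0.196), exp(0.196)), tolerance = 1e-12)
  expect_equal(unname(to_odds_ratio(0, 0)), c(1, 1, 1))
  # a published-style OR/CI row is reproduced from its log-scale inputs
  beta <- log(1.119)
  se <- (log(1.223) - log(1.024)) / (2 * 1.96)
  ci <- to_odds_ratio(beta, se)
  expect_equal(round(unname(ci), 3), c(1.119, 1.024, 1.223))
})

test_that("estimators are scale- and sign-equivariant", {
  study <- simulate_study(sim_config(n_snps = 30, beta_causal = 0.15,
                                     seed = 14))
  h <- harmonize_study(study)
  d <- kept_rows(h)
  point <- function(hh) c(mr_ivw(hh)$beta, mr_egger(hh)$beta,
                          mr_weighted_median(hh, n_boot = 0)$beta)
  mode_point <- function(hh) mr_weighted_mode(hh, n_boot = 0)$beta
  base <- point(h)
  base_mode <- mode_point(h)

  # multiplying exposure effects by c divides every estimate by c
  h_scaled <- hset(d$beta_exp * 2, d$se_exp * 2, d$beta_out, d$se_out)
  expect_equal(point(h_scaled), base / 2, tolerance = 1e-8)
  expect_equal(mode_point(h_scaled), base_mode / 2, tolerance = 1e-8)

  # negating outcome effects negates every estimate, SEs unchanged;
  # the mode is grid-based, so it is symmetric only to grid resolution
  h_neg <- hset(d$beta_exp, d$se_exp, -d$beta_out, d$se_out)
  expect_equal(point(h_neg), -base, tolerance = 1e-8)
  expect_equal(mode_point(h_neg), -base_mode, tolerance = 2e-3)
  expect_equal(mr_ivw(h_neg)$se, mr_ivw(h)$se, tolerance = 1e-12)
  expect_equal(mr_egger(h_neg)$se, mr_egger(h)$se, tolerance = 1e-12)
})
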