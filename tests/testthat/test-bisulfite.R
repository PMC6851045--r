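# Methylation quantification, conversion correction, site calling, the
# empirical Bayes moderated t-test, reference conversion and clone scoring.

test_that("methylation level is the unconverted fraction with NA at zero
           coverage", {
  expect_equal(methylation_level(95, 100), 0.95)
  expect_equal(methylation_level(0, 100), 0)
  expect_true(is.na(methylation_level(0, 0)))
  expect_error(methylation_level(7, 0), "exceeds coverage")
  expect_error(methylation_level(-1, 5), "non-negative")
})

test_that("conversion efficiency pools control sites; correction inverts the
           forward model", {
  pile <- data.frame(site = c(1, 1, 2, 2, 3),
                     coverage = c(1000, 600, 300, 100, 50),
                     unconverted = c(12, 5, 2, 1, 49))
  expect_equal(estimate_conversion_efficiency(pile, c(1, 2)),
               1 - 20 / 2000)
  expect_equal(estimate_conversion_efficiency(pile, 1:2), 0.99)
  expect_error(estimate_conversion_efficiency(
    data.frame(site = 1, coverage = 0, unconverted = 0), 1),
    "no covered control sites")

  expect_equal(correct_for_conversion(0.9505, 0.99), 0.95)
  expect_equal(correct_for_conversion(0.42, 1), 0.42)
  expect_warning(out <- correct_for_conversion(0.005, 0.99), "clipped")
  expect_equal(out, 0)
  expect_error(correct_for_conversion(0.5, 0), "\\(0, 1\\]")

  # round trip: forward model then correction is the identity on [0, 1]
  m <- seq(0, 1, by = 0.05)
  for (e in c(0.9, 0.99, 1)) {
    obs <- m + (1 - m) * (1 - e)
    expect_equal(correct_for_conversion(obs, e), m, tolerance = 1e-12)
  }
})

test_that("high-methylation site calling is strict, coverage-filtered and
           finds exactly the planted site", {
  pile <- simulate_bsrna_pileup(bs_sim_config(
    n_sites = 999, planted_site_index = 500, seed = 2))
  hits <- call_high_methylation_sites(pile, "NSUN5", threshold = 0.9,
                                      min_coverage = 30, efficiency = 0.99)
  expect_identical(hits$site, 500L)
  # the same site is not called in the unmethylated arm
  expect_identical(nrow(call_high_methylation_sites(
    pile, "EV", threshold = 0.9, efficiency = 0.99)), 0L)
  expect_error(call_high_methylation_sites(pile, "KD"), "absent")

  # a site at exactly the threshold is excluded ("over 90%" is strict)
  flat <- data.frame(site = c(1L, 2L), library = "l1", condition = "A",
                     coverage = c(100L, 100L), unconverted = c(90L, 91L))
  out <- call_high_methylation_sites(flat, "A", threshold = 0.9,
                                     min_coverage = 10)
  expect_identical(out$site, 2L)
  # min_coverage above every pooled coverage: empty call set
  expect_identical(nrow(call_high_methylation_sites(
    flat, "A", min_coverage = 1000)), 0L)
})

test_that("prior fitting: degenerate equality, recovery, and minimal input", {
  pr <- fit_moderated_prior(rep(0.02, 20), residual_df = 4)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_squared, 0.02)

  # variances from the scaled-F marginal with d0 = 4, s0^2 = 0.02
  set.seed(8)
  d <- 4; d0 <- 4; s0 <- 0.02
  sigma2 <- s0 * d0 / rchisq(2000, d0)       # scaled inverse chi-square
  s2 <- sigma2 * rchisq(2000, d) / d
  fit <- fit_moderated_prior(s2, residual_df = d)
  expect_gt(fit$d0, 2.5); expect_lt(fit$d0, 6)
  expect_gt(fit$s0_squared, 0.015); expect_lt(fit$s0_squared, 0.026)

  expect_message(two <- fit_moderated_prior(c(0.01, 0.03), 4),
                 "low-confidence")
  expect_true(is.finite(two$s0_squared))
})

test_that("prior fit agrees with limma's empirical Bayes moment estimator", {
  skip_if_not_installed("limma")
  set.seed(9)
  s2 <- 0.05 * 6 / rchisq(500, 6) * rchisq(500, 4) / 4
  ours <- fit_moderated_prior(s2, 4)
  ref <- limma::squeezeVar(s2, df = 4)
  expect_equal(ours$d0, ref$df.prior, tolerance = 0.05)
  expect_equal(ours$s0_squared, ref$var.prior, tolerance = 0.02)
})

test_that("moderated t reduces to the ordinary pooled t at d0 = 0 and to the
           prior variance at d0 = Inf", {
  a <- matrix(c(0.10, 0.15, 0.12), nrow = 1)
  b <- matrix(c(0.30, 0.24, 0.28), nrow = 1)
  prior0 <- structure(list(s0_squared = 0.5, d0 = 0),
                      class = "ModeratedTPrior")
  got <- moderated_t_site_test(a, b, prior0)
  orc <- oracle_pooled_t(asin(sqrt(a[1, ])), asin(sqrt(b[1, ])))
  expect_equal(got$moderated_t, orc$t, tolerance = 1e-10)
  expect_equal(got$p_value, orc$p, tolerance = 1e-10)
  expect_equal(got$df_total, orc$df)

  # untransformed mode against the same textbook statistic
  got_raw <- moderated_t_site_test(a, b, prior0, transform = "none")
  orc_raw <- oracle_pooled_t(a[1, ], b[1, ])
  expect_equal(got_raw$moderated_t, orc_raw$t, tolerance = 1e-10)

  prior_inf <- structure(list(s0_squared = 0.01, d0 = Inf),
                         class = "ModeratedTPrior")
  got_inf <- moderated_t_site_test(a, b, prior_inf, transform = "none")
  expect_equal(got_inf$moderated_t,
               (mean(b) - mean(a)) / sqrt(0.01 * (1 / 3 + 1 / 3)),
               tolerance = 1e-10)

  # identical replicate vectors: t = 0, p = 1
  same <- moderated_t_site_test(a, a, prior0)
  expect_equal(same$moderated_t, 0)
  expect_equal(same$p_value, 1)
})

test_that("moderated t null type-I error is calibrated at alpha = 0.05", {
  set.seed(12)
  nsite <- 2000; nrep <- 3; cov <- 100; m <- 0.1
  lvA <- matrix(rbinom(nsite * nrep, cov, m) / cov, nsite)
  lvB <- matrix(rbinom(nsite * nrep, cov, m) / cov, nsite)
  res <- moderated_t_site_test(lvA, lvB)
  rate <- mean(res$p_value < 0.05, na.rm = TRUE)
  env <- 2.576 * sqrt(0.05 * 0.95 / nsite)
  expect_lt(abs(rate - 0.05), env + 0.01)  # binomial noise + t approximation
})

test_that("reference conversion follows the bisulfite chemistry rules", {
  expect_identical(convert_reference("ACGT", "all_c"), "ATGT")
  expect_identical(convert_reference("ACGT", "cpg_only"), "ACGT")
  expect_identical(convert_reference("CCGG", "cpg_only"), "TCGG")
  expect_identical(convert_reference("acgu", "all_c"), "ATGT")  # RNA input
  expect_error(convert_reference("ACXT", "all_c"), "position")
})

test_that("clone scoring counts calls and excludes ambiguous bases", {
  ref <- "ACGTCAC"            # queried Cs (all_c) at 2, 5, 7
  clones <- c(c1 = "ACGTCAC", c2 = "ATGTTAT", c3 = "ACGTGAC")
  expect_warning(cm <- clone_analysis(clones, ref, "all_c"),
                 "minimum advised")
  expect_identical(cm$positions, c(2L, 5L, 7L))
  expect_identical(unname(cm$calls["c2", ]),
                   rep("unmethylated", 3))
  expect_identical(unname(cm$calls["c3", "C5"]), "ambiguous")
  # position 5: c1 methylated, c2 unmethylated, c3 ambiguous -> 1/2
  expect_equal(unname(cm$per_position_frequency["C5"]), 0.5)
  expect_equal(unname(cm$per_clone_percent["c1"]), 1)
  expect_error(clone_analysis(c(bad = "ACGT"), ref), "bad")
})

test_that("simulate_clones -> clone_analysis round trip recovers the truth", {
  amp <- "CCGTACGTTCAGGCATCGAC"   # cytosines at 1, 2, 6, 10, 14, 17, 20
  m_truth <- c(1, 0, 0, 1, 0, 1, 1)
  cl <- simulate_clones(clone_sim_config(amp, "all_c", n_clones = 12,
                                         per_site_methylation = m_truth,
                                         sequencing_error_rate = 0,
                                         seed = 4))
  cm <- clone_analysis(cl$clones, amp, "all_c")
  # degenerate probabilities recover exactly
  expect_equal(unname(cm$per_position_frequency), m_truth)

  # m = 0.5: mean frequency over reseeds within 3 binomial SE
  freqs <- vapply(1:300, function(s) {
    cl <- simulate_clones(clone_sim_config("AACGTA", "all_c", n_clones = 8,
                                           per_site_methylation = 0.5,
                                           seed = 5000 + s))
    unname(clone_analysis(cl$clones, "AACGTA",
                          "all_c")$per_position_frequency)
  }, numeric(1))
  se <- sqrt(0.25 / 8) / sqrt(300)
  expect_lt(abs(mean(freqs) - 0.5), 3 * se)
})

test_that("pileup level matrices align sites and feed the moderated test", {
  pile <- simulate_bsrna_pileup(bs_sim_config(n_sites = 200,
                                              planted_site_index = 42,
                                              seed = 13))
  lv <- pileup_level_matrices(pile)
  expect_identical(dim(lv$levels_A), c(200L, 3L))
  res <- moderated_t_site_test(lv$levels_A, lv$levels_B, sites = lv$sites)
  expect_identical(res$site[which.min(res$p_value)], 42L)
  expect_gt(res$mean_level_B[res$site == 42], 0.9)
})
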