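# Dispersion estimation, the per-transcript NB Wald test, the enhanced-TE
# classification, the interaction test and BH adjustment.

make_ce <- function(counts, condition = NULL, lengths = NULL,
                    assay = "rna") {
  if (is.null(condition))
    condition <- rep(c("EV", "NSUN5"), each = ncol(counts) / 2)
  if (is.null(lengths)) lengths <- rep(1000L, nrow(counts))
  count_experiment(counts, lengths, condition, assay = assay)
}

test_that("method-of-moments dispersion matches the direct formula and the
           Poisson limit", {
  # 6-library toy, one condition informative; size factors are all 1 by
  # symmetry so normalized counts equal raw counts
  y <- rbind(c(10, 14, 18, 10, 14, 18),
             c(100, 140, 90, 100, 140, 90))
  cond <- rep(c("A", "B"), each = 3)
  norm <- sweep(y, 2, oracle_size_factors(y), "/")
  raw_expected <- vapply(1:2, function(i) {
    per_cond <- vapply(c("A", "B"), function(l) {
      x <- norm[i, cond == l]
      (var(x) - mean(x)) / mean(x)^2
    }, numeric(1))
    mean(per_cond)  # equal weights: both conditions have 3 libraries
  }, numeric(1))
  got <- estimate_dispersion(y, cond, shrinkage = 0)
  expect_equal(as.numeric(got), pmax(raw_expected, 1e-8), tolerance = 1e-10)

  # variance == mean in both conditions -> floored at 1e-8
  yp <- rbind(c(4, 5, 6, 4, 5, 6))   # var 1, mean 5 -> raw (1-5)/25 < 0
  dp <- estimate_dispersion(rbind(yp, yp + 0L), cond, shrinkage = 0)
  expect_equal(as.numeric(dp), c(1e-8, 1e-8))
})

test_that("dispersion recovery on simulated NB data at alpha = 0.1", {
  cfg <- te_sim_config(n_transcripts = 300, n_reps_per_condition = 25,
                       dispersion = 0.1, baseline_log2_mean = 7,
                       baseline_log2_sd = 1, frac_rna_de = 0,
                       frac_te_up = 0, seed = 21)
  sim <- simulate_te_experiment(cfg)
  d <- estimate_dispersion(sim$rna, shrinkage = 0)
  expect_gt(median(d), 0.07)
  expect_lt(median(d), 0.13)
})

test_that("Wald test: symmetry, all-zero convention, and agreement with a
           grid-search ML oracle", {
  y <- rbind(c(50, 60, 55, 50, 60, 55),
             c(0, 0, 0, 0, 0, 0),
             c(30, 35, 40, 70, 80, 90))
  ce <- make_ce(y)
  res <- differential_abundance(ce, dispersions = 0.05,
                                size_factors = rep(1, 6))
  expect_equal(res$log2fc[1], 0, tolerance = 1e-9)
  expect_equal(res$p_value[1], 1, tolerance = 1e-9)
  expect_identical(res$log2fc[2], 0)
  expect_identical(res$p_value[2], 1)
  expect_identical(res$base_mean[2], 0)

  # 1 library per condition, 1 transcript: z must equal the hand ratio of
  # the independently fitted MLEs and their Fisher variances
  y1 <- matrix(c(40L, 95L), nrow = 1)
  ce1 <- make_ce(y1, condition = c("A", "B"))
  alpha <- 0.07
  r1 <- differential_abundance(ce1, dispersions = alpha,
                               size_factors = c(1, 1))
  bA <- oracle_nb_mle(40, 1, alpha); bB <- oracle_nb_mle(95, 1, alpha)
  se <- sqrt(1 / oracle_nb_info(bA, 1, alpha) +
             1 / oracle_nb_info(bB, 1, alpha))
  expect_equal(r1$log2fc, (bB - bA) / log(2), tolerance = 1e-6)
  expect_equal(r1$log2fc / r1$se_log2fc, (bB - bA) / se, tolerance = 1e-6)
  expect_equal(r1$p_value, 2 * pnorm(-abs((bB - bA) / se)),
               tolerance = 1e-6)

  # multi-library fit agrees with the grid-search oracle too
  yg <- matrix(c(12L, 20L, 9L, 31L, 40L, 36L), nrow = 1)
  sfg <- c(0.8, 1.1, 1.0, 0.9, 1.2, 1.05)
  ceg <- make_ce(yg)
  rg <- differential_abundance(ceg, dispersions = 0.1, size_factors = sfg)
  bA <- oracle_nb_mle(c(12, 20, 9), sfg[1:3], 0.1)
  bB <- oracle_nb_mle(c(31, 40, 36), sfg[4:6], 0.1)
  expect_equal(rg$log2fc, (bB - bA) / log(2), tolerance = 1e-6)
})

test_that("enhanced-TE classification applies the printed thresholds", {
  thr <- te_thresholds()  # |RNA log2FC| > 2; Ribo p < 0.01 & |log2FC| > 0.5
  rna <- make_result(c("t1", "t2", "t3"), c(0.1, 2.5, 0.3),
                     c(0.5, 1e-5, 0.9))
  ribo <- make_result(c("t1", "t2", "t3"), c(1.0, 1.0, 0.6),
                      c(0.001, 0.001, 0.02))
  cls <- classify_te(rna, ribo, thr)
  expect_identical(cls$enhanced_te, c(TRUE, FALSE, FALSE))
  expect_identical(as.character(cls$rna_status),
                   c("unchanged", "up", "unchanged"))
  expect_identical(as.character(cls$occupancy_status),
                   c("up", "up", "unchanged"))  # t3 fails p < 0.01
})

test_that("transcripts present in one assay only are excluded with a message", {
  rna <- make_result(c("a", "b"), c(0, 0), c(1, 1))
  ribo <- make_result(c("b", "c"), c(1, 1), c(0.001, 0.001))
  expect_message(cls <- classify_te(rna, ribo), "excluded")
  expect_identical(cls$transcript_id, "b")
})

test_that("loosening any threshold grows the enhanced-TE set", {
  set.seed(31)
  n <- 400
  rna <- make_result(paste0("t", 1:n), rnorm(n, 0, 2), runif(n))
  ribo <- make_result(paste0("t", 1:n), rnorm(n, 0.3, 1), runif(n)^2)
  base <- classify_te(rna, ribo, te_thresholds())
  for (thr in list(te_thresholds(rna_abs_log2fc = 3),
                   te_thresholds(ribo_abs_log2fc = 0.25),
                   te_thresholds(ribo_p = 0.05))) {
    loose <- classify_te(rna, ribo, thr)
    expect_true(all(loose$enhanced_te[base$enhanced_te]))
  }
})

test_that("interaction coefficient is ribo log2FC minus rna log2FC and
           vanishes on identical cells", {
  y <- matrix(rep(c(40L, 50L, 45L), 4), nrow = 1)
  dimnames(y) <- list("t1", paste0("l", 1:12))
  rna <- make_ce(y[, 1:6, drop = FALSE])
  ribo <- make_ce(y[, 7:12, drop = FALSE], assay = "ribo")
  r <- glm_te_interaction(rna, ribo, dispersions = 0.1)
  expect_equal(r$delta_te_log2, 0, tolerance = 1e-9)

  # noiseless expected counts: exact additivity
  mu_rna <- c(100, 100, 100, 200, 200, 200)       # rna log2fc = 1
  mu_ribo <- c(100, 100, 100, 800, 800, 800)      # ribo log2fc = 3
  rna2 <- make_ce(matrix(as.integer(mu_rna), nrow = 1))
  ribo2 <- make_ce(matrix(as.integer(mu_ribo), nrow = 1), assay = "ribo")
  sf1 <- rep(1, 6)
  ra <- differential_abundance(rna2, 0.05, sf1)
  rb <- differential_abundance(ribo2, 0.05, sf1)
  r2 <- glm_te_interaction(rna2, ribo2, dispersions = 0.05,
                           size_factors_rna = sf1, size_factors_ribo = sf1)
  expect_equal(r2$delta_te_log2, 3 - 1, tolerance = 1e-6)
  expect_equal(r2$delta_te_log2, rb$log2fc - ra$log2fc, tolerance = 1e-6)
})

test_that("interaction estimate recovers a planted TE shift of 1 log2 unit", {
  ests <- numeric(0)
  for (s in 1:4) {
    sim <- simulate_te_experiment(te_sim_config(
      n_transcripts = 1000, n_reps_per_condition = 3, dispersion = 0.05,
      baseline_log2_mean = 7, frac_rna_de = 0, frac_te_up = 0.05,
      te_log2fc = 1, seed = 100 + s))
    r <- glm_te_interaction(sim$rna, sim$ribo, dispersions = 0.05)
    ests <- c(ests, r$delta_te_log2[sim$truth$planted_class == "te_up"])
  }
  expect_gte(length(ests), 200)
  expect_gt(mean(ests), 0.9)
  expect_lt(mean(ests), 1.1)
})

test_that("degenerate interaction designs are rejected", {
  y <- matrix(rpois(12, 50), nrow = 2,
              dimnames = list(c("a", "b"), paste0("l", 1:6)))
  rna <- make_ce(y)
  ribo <- make_ce(y[2:1, ], assay = "ribo")  # reordered ids
  expect_error(glm_te_interaction(rna, ribo, 0.1), "share transcripts")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.04), 0.04)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone consistency with the sorted order
  set.seed(4)
  p <- runif(50)
  adj <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})

test_that("classification pipeline is invariant to rescaling one library", {
  sim <- simulate_te_experiment(te_sim_config(
    n_transcripts = 300, baseline_log2_mean = 7, seed = 51))
  run <- function(rna, ribo) {
    ra <- differential_abundance(rna, dispersions = 0.1)
    rb <- differential_abundance(ribo, dispersions = 0.1)
    classify_te(ra, rb)
  }
  base <- run(sim$rna, sim$ribo)
  rna2 <- sim$rna
  rna2$counts[, 2] <- rna2$counts[, 2] * 5L
  scaled <- run(count_experiment(rna2$counts, rna2$lengths_bp,
                                 rna2$condition), sim$ribo)
  agree <- mean(base$enhanced_te == scaled$enhanced_te)
  expect_gt(agree, 0.99)
})
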