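# Cytosine methylation from bisulfite pileups: quantification, conversion
# correction, high-methylation site calling, and the empirical Bayes
# moderated t-test for differential site methylation. Site coordinates are
# 1-based throughout, matching the rRNA convention (e.g. "C3782").

#' Methylation level from unconverted and total counts
#'
#' `unconverted / coverage`, elementwise. Sites with zero coverage return
#' `NA` (missing, not 0): absence of reads is not absence of methylation.
#'
#' @param unconverted,coverage Non-negative integer vectors, recycled.
#' @return Numeric vector of proportions (NA where coverage is 0).
#' @examples
#' methylation_level(95, 100)   # 0.95
#' methylation_level(0, 100)    # 0
#' @export
methylation_level <- function(unconverted, coverage) {
  n <- max(length(unconverted), length(coverage))
  unconverted <- rep_len(unconverted, n)
  coverage <- rep_len(coverage, n)
  if (any(unconverted < 0) || any(coverage < 0))
    stop("counts must be non-negative")
  if (any(unconverted > coverage))
    stop("unconverted count exceeds coverage")
  ifelse(coverage == 0, NA_real_, unconverted / coverage)
}

#' Bisulfite conversion efficiency from control sites
#'
#' Pools coverage and unconverted counts over declared known-unmethylated
#' control sites: efficiency = 1 - pooled unconverted / pooled coverage.
#'
#' @param pileup A pileup data.frame with columns `site`, `coverage`,
#'   `unconverted` (e.g. from [simulate_bsrna_pileup()]).
#' @param control_sites 1-based coordinates of known-unmethylated sites.
#' @return Efficiency in `[0, 1]`.
#' @export
estimate_conversion_efficiency <- function(pileup, control_sites) {
  sel <- pileup$site %in% control_sites & pileup$coverage > 0
  if (!any(sel))
    stop("no covered control sites")
  1 - sum(pileup$unconverted[sel]) / sum(pileup$coverage[sel])
}

#' Correct observed methylation for incomplete bisulfite conversion
#'
#' Inverts the forward model `observed = m + (1 - m) * (1 - e)`:
#' `m = (observed - (1 - e)) / e`, clipped to `[0, 1]` with a warning when
#' clipping occurs. With perfect conversion (`e = 1`) the observed level is
#' returned unchanged.
#'
#' @param observed_level Observed proportion(s).
#' @param efficiency Conversion efficiency in `(0, 1]`.
#' @return Corrected proportion(s).
#' @export
correct_for_conversion <- function(observed_level, efficiency) {
  if (length(efficiency) != 1 || efficiency <= 0 || efficiency > 1)
    stop("'efficiency' must be a single value in (0, 1]")
  m <- (observed_level - (1 - efficiency)) / efficiency
  if (any(m < 0 | m > 1, na.rm = TRUE))
    warning("corrected level clipped to [0, 1] at ",
            sum(m < 0 | m > 1, na.rm = TRUE), " value(s)")
  pmin(pmax(m, 0), 1)
}

#' Call sites exceeding a methylation threshold
#'
#' Pools counts across the replicate libraries of one condition, corrects
#' the pooled level for conversion efficiency, and returns the sites whose
#' corrected level *strictly* exceeds `threshold` ("over 90%" is a strict
#' inequality) with pooled coverage at least `min_coverage`, sorted by
#' level descending.
#'
#' @param pileup Pileup data.frame (`site`, `condition`, `coverage`,
#'   `unconverted`).
#' @param condition Condition whose libraries are pooled.
#' @param threshold Methylation cutoff in (0, 1); default 0.9.
#' @param min_coverage Minimum pooled coverage (default 30).
#' @param efficiency Conversion efficiency used for correction (default 1 =
#'   no correction); see [estimate_conversion_efficiency()].
#' @return data.frame with `site`, `coverage` (pooled), `level` (corrected).
#' @export
call_high_methylation_sites <- function(pileup, condition, threshold = 0.9,
                                        min_coverage = 30, efficiency = 1) {
  stopifnot(threshold > 0, threshold < 1, min_coverage >= 1)
  if (!condition %in% as.character(pileup$condition))
    stop("condition '", condition, "' absent from pileup")
  sub <- pileup[as.character(pileup$condition) == condition, , drop = FALSE]
  cov <- tapply(sub$coverage, sub$site, sum)
  unc <- tapply(sub$unconverted, sub$site, sum)
  site <- as.integer(names(cov))
  keep <- cov >= min_coverage
  level <- suppressWarnings(
    correct_for_conversion(methylation_level(unc[keep], cov[keep]),
                           efficiency))
  hit <- !is.na(level) & level > threshold
  out <- data.frame(site = site[keep][hit],
                    coverage = as.integer(cov[keep][hit]),
                    level = level[hit])
  out[order(-out$level), , drop = FALSE]
}

# Solve trigamma(x) = y for x > 0 (Newton; trigamma is decreasing convex).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Fit the empirical Bayes variance prior
#'
#' Models per-site sample variances as `s^2 ~ s0^2 * F(d, d0)` (the scaled
#' F marginal of a scaled inverse chi-square prior on the true variances)
#' and recovers the prior scale `s0^2` and degrees of freedom `d0` by
#' moment matching on `log s^2`: the spread of log variances in excess of
#' the chi-square sampling noise `trigamma(d/2)` determines `d0` through
#' trigamma inversion. Near-constant variances give `d0 = Inf` (complete
#' shrinkage).
#'
#' @param site_variances Per-site sample variances (positive; NA dropped).
#' @param residual_df Residual degrees of freedom of each variance (scalar
#'   or vector).
#' @return A `ModeratedTPrior` list with `s0_squared`, `d0`, and `n_sites`.
#' @export
fit_moderated_prior <- function(site_variances, residual_df) {
  s2 <- site_variances[is.finite(site_variances) & site_variances > 0]
  df <- rep_len(residual_df, length(site_variances))
  df <- df[is.finite(site_variances) & site_variances > 0]
  if (length(s2) < 2) {
    if (all(site_variances == 0, na.rm = TRUE)) {
      warning("all site variances are zero; using d0 = Inf with a floor prior")
      return(structure(list(s0_squared = 1e-8, d0 = Inf, n_sites = 0L),
                       class = "ModeratedTPrior"))
    }
    stop("need >= 2 finite positive sample variances")
  }
  if (length(s2) == 2)
    message("only two variances available; prior estimate is low-confidence")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  if (isTRUE(all.equal(var(log(s2)), 0, tolerance = 1e-12))) {
    # exactly constant variances: no information about d0, prior = common value
    return(structure(list(s0_squared = s2[1], d0 = Inf,
                          n_sites = length(s2)),
                     class = "ModeratedTPrior"))
  }
  evar <- var(e) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(mean(e))
  }
  structure(list(s0_squared = s0, d0 = d0, n_sites = length(s2)),
            class = "ModeratedTPrior")
}

#' @export
print.ModeratedTPrior <- function(x, ...) {
  cat(sprintf("ModeratedTPrior: s0^2 = %.4g, d0 = %s (from %d sites)\n",
              x$s0_squared, format(x$d0), x$n_sites))
  invisible(x)
}

#' Empirical Bayes moderated t-test for differential site methylation
#'
#' Per site, replicate methylation levels are variance-stabilized
#' (arcsine-square-root by default), the sample variance is pooled across
#' the two conditions, and shrunk toward the prior:
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`. The moderated statistic is
#' `t = (mean_B - mean_A) / (s~ * sqrt(1/nA + 1/nB))` on `d0 + d` degrees
#' of freedom. With `d0 = 0` this is the ordinary pooled-variance
#' two-sample t-test; with `d0 = Inf` the denominator uses `s0^2` alone.
#'
#' @param levels_A,levels_B Matrices of per-site replicate methylation
#'   levels (sites x replicates; proportions in `[0, 1]`, NA allowed), rows
#'   aligned across conditions.
#' @param prior A `ModeratedTPrior`; fitted from the pooled variances of
#'   these data when `NULL`.
#' @param sites Optional site coordinates (default row order).
#' @param transform `"asin_sqrt"` (default) or `"none"` (raw proportions).
#' @return data.frame with `site`, `mean_level_A`, `mean_level_B`, `delta`,
#'   `moderated_t`, `df_total`, `p_value`, `fdr`. Sites with fewer than 2
#'   usable replicates in total (or no residual df) get NA statistics.
#' @export
moderated_t_site_test <- function(levels_A, levels_B, prior = NULL,
                                  sites = NULL,
                                  transform = c("asin_sqrt", "none")) {
  transform <- match.arg(transform)
  levels_A <- as.matrix(levels_A)
  levels_B <- as.matrix(levels_B)
  if (nrow(levels_A) != nrow(levels_B))
    stop("'levels_A' and 'levels_B' must have the same number of sites")
  if (is.null(sites)) sites <- seq_len(nrow(levels_A))
  tr <- if (transform == "asin_sqrt") function(p) asin(sqrt(p)) else identity
  yA <- tr(levels_A); yB <- tr(levels_B)
  nA <- rowSums(!is.na(yA)); nB <- rowSums(!is.na(yB))
  mA <- rowMeans(yA, na.rm = TRUE); mB <- rowMeans(yB, na.rm = TRUE)
  ssA <- rowSums((yA - mA)^2, na.rm = TRUE)
  ssB <- rowSums((yB - mB)^2, na.rm = TRUE)
  df <- nA + nB - 2
  ok <- nA >= 1 & nB >= 1 & df >= 1
  if (any(!ok))
    message(sum(!ok), " site(s) with insufficient replication; NA returned")
  s2 <- ifelse(ok, (ssA + ssB) / pmax(df, 1), NA_real_)
  if (is.null(prior))
    prior <- fit_moderated_prior(s2[ok], df[ok])
  d0 <- prior$d0; s0 <- prior$s0_squared
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2))
             else (d0 * s0 + df * s2) / (d0 + df)
  tstat <- (mB - mA) / sqrt(s2_post * (1 / nA + 1 / nB))
  df_tot <- d0 + df
  p <- 2 * pt(-abs(tstat), df = df_tot)
  tstat[!ok] <- NA_real_; p[!ok] <- NA_real_
  res <- data.frame(
    site = sites,
    mean_level_A = rowMeans(levels_A, na.rm = TRUE),
    mean_level_B = rowMeans(levels_B, na.rm = TRUE),
    moderated_t = tstat,
    df_total = df_tot,
    p_value = p,
    stringsAsFactors = FALSE
  )
  res$delta <- res$mean_level_B - res$mean_level_A
  res$fdr <- bh_fdr(ifelse(is.na(p), 1, p))
  res$fdr[is.na(p)] <- NA_real_
  res[, c("site", "mean_level_A", "mean_level_B", "delta", "moderated_t",
          "df_total", "p_value", "fdr")]
}

#' Per-site replicate methylation levels from a pileup
#'
#' Reshapes a long pileup into two sites x replicates level matrices (one
#' per condition), suitable for [moderated_t_site_test()].
#'
#' @param pileup Pileup data.frame (`site`, `library`, `condition`,
#'   `coverage`, `unconverted`) with exactly two condition levels.
#' @param efficiency Conversion efficiency applied to each level.
#' @return list with `sites`, `levels_A`, `levels_B`, `conditions`.
#' @export
pileup_level_matrices <- function(pileup, efficiency = 1) {
  cond <- as.factor(pileup$condition)
  if (nlevels(cond) != 2) stop("pileup must have exactly two conditions")
  sites <- sort(unique(pileup$site))
  one <- function(lev) {
    sub <- pileup[cond == lev, , drop = FALSE]
    libs <- unique(sub$library)
    m <- sapply(libs, function(lb) {
      s <- sub[sub$library == lb, ]
      lvl <- suppressWarnings(correct_for_conversion(
        methylation_level(s$unconverted, s$coverage), efficiency))
      lvl[match(sites, s$site)]
    })
    matrix(m, nrow = length(sites), dimnames = list(NULL, libs))
  }
  list(sites = sites,
       levels_A = one(levels(cond)[1]),
       levels_B = one(levels(cond)[2]),
       conditions = levels(cond))
}
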