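#' Median-of-ratios size factors
#'
#' Estimates one positive scaling factor per library by the median-of-ratios
#' method: each library's counts are divided by the per-transcript geometric
#' mean across libraries (computed over transcripts with no zero count), and
#' the library's factor is the median of those ratios. When no transcript is
#' positive in every library the function falls back to total-count ratios
#' (each library total over the geometric mean of totals) with a warning.
#'
#' @param counts Non-negative count matrix, transcripts x libraries, or a
#'   [count_experiment()] object.
#' @return Numeric vector of positive size factors, one per library.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' estimate_size_factors(m)  # ratios 1 : 2, geometric mean 1
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "CountExperiment")) counts <- counts$counts
  counts <- as.matrix(counts)
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) {
    warning("no transcript with all-positive counts; ",
            "falling back to total-count size factors")
    tot <- colSums(counts)
    if (any(tot == 0)) stop("library with zero total count")
    return(tot / exp(mean(log(tot))))
  }
  logref <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2,
              function(y) median(exp(log(y) - logref)))
  unname(sf)
}

#' Reads per kilobase per million (RPKM)
#'
#' Normalizes counts to transcript length and sequencing depth:
#' `count / (effective library size / 1e6) / (length / 1e3)`. The effective
#' library size of library *j* is `size_factor_j * K`, where `K` is the mean
#' across libraries of the depth-normalized totals `sum(counts[, j]) /
#' size_factor_j`; this makes RPKM exactly invariant to rescaling any one
#' library's counts (the rescaling is absorbed by its size factor).
#'
#' @param counts Count matrix, transcripts x libraries.
#' @param lengths_bp Transcript lengths in bp.
#' @param size_factors Per-library size factors; estimated by
#'   [estimate_size_factors()] when missing.
#' @return Matrix of RPKM values with the dimensions of `counts`.
#' @examples
#' rpkm(matrix(100), lengths_bp = 1000, size_factors = 1)  # if the library
#' # has 1e6 reads this is 100; here the single count defines the depth
#' @export
rpkm <- function(counts, lengths_bp, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (any(lengths_bp <= 0)) stop("'lengths_bp' must be positive")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  depth <- colSums(counts) / size_factors
  eff <- size_factors * mean(depth)
  if (any(eff <= 0)) stop("zero effective library size")
  sweep(counts, 2, eff / 1e6, "/") / (lengths_bp / 1e3)
}

#' Translational efficiency from RPKM matrices
#'
#' TE is ribosome occupancy normalized to transcript abundance:
#' `(ribo_rpkm + pseudocount) / (rna_rpkm + pseudocount)`, elementwise over
#' aligned matrices. The pseudocount bounds the ratio when either assay is
#' zero; with `pseudocount = 0` and both values zero the result would be
#' undefined, so a positive pseudocount is recommended for sparse data.
#'
#' @param rna_rpkm,ribo_rpkm Aligned RPKM matrices (same transcripts in the
#'   same order; columns are libraries or condition means).
#' @param pseudocount Non-negative value added to both numerator and
#'   denominator (default 0.5).
#' @return Matrix of TE ratios.
#' @export
compute_te <- function(rna_rpkm, ribo_rpkm, pseudocount = 0.5) {
  rna_rpkm <- as.matrix(rna_rpkm)
  ribo_rpkm <- as.matrix(ribo_rpkm)
  if (!all(dim(rna_rpkm) == dim(ribo_rpkm)))
    stop("RNA and Ribo RPKM matrices must have the same shape")
  if (pseudocount < 0) stop("'pseudocount' must be non-negative")
  (ribo_rpkm + pseudocount) / (rna_rpkm + pseudocount)
}

#' Per-transcript NB dispersion with trend shrinkage
#'
#' Estimates the negative binomial dispersion `alpha` (variance =
#' `mu + alpha * mu^2`) per transcript by a within-condition method of
#' moments on size-factor-normalized counts — the raw estimate in a
#' condition with sample mean `m` and variance `v` is `(v - m) / m^2` — then
#' shrinks the (zero-floored) raw values toward a fitted mean-dispersion
#' trend `a0 + a1 / mean`. Raw estimates are pooled across conditions with
#' weights `n_c - 1`.
#'
#' @param experiment A [count_experiment()] object, or a count matrix (then
#'   `condition` is required).
#' @param condition Two-level factor over libraries when `experiment` is a
#'   bare matrix.
#' @param shrinkage Weight in `[0, 1]` on the trend (0 = raw method of
#'   moments, 1 = pure trend). Default 0.5.
#' @param floor Lower bound for the returned dispersions (default 1e-8);
#'   Poisson-like data lands on the floor.
#' @return Numeric vector of dispersions, one per transcript, with an
#'   `eff_df` attribute: the Satterthwaite-style effective degrees of
#'   freedom of the shrunk estimate, `residual df / (1 - shrinkage)^2`.
#'   Downstream Wald tests use a t reference on these df instead of the
#'   normal, which keeps the extreme tail of the null calibrated when
#'   dispersions are estimated from few replicates.
#' @export
estimate_dispersion <- function(experiment, condition = NULL,
                                shrinkage = 0.5, floor = 1e-8) {
  if (inherits(experiment, "CountExperiment")) {
    counts <- experiment$counts
    condition <- experiment$condition
  } else {
    counts <- as.matrix(experiment)
    if (is.null(condition)) stop("'condition' required with a bare matrix")
    condition <- as.factor(condition)
  }
  if (ncol(counts) < 2) stop("dispersion estimation needs >= 2 libraries")
  if (!any(table(condition) >= 2))
    stop("dispersion estimation needs >= 2 libraries in some condition")
  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  num <- rep(0, nrow(counts)); den <- 0
  means <- rowMeans(norm)
  for (lev in levels(condition)) {
    j <- condition == lev
    n_c <- sum(j)
    if (n_c < 2) next
    m <- rowMeans(norm[, j, drop = FALSE])
    v <- apply(norm[, j, drop = FALSE], 1, var)
    raw_c <- ifelse(m > 0, (v - m) / m^2, 0)
    num <- num + (n_c - 1) * raw_c
    den <- den + (n_c - 1)
  }
  raw <- num / den
  raw_f <- pmax(raw, 0)
  # mean-dispersion trend alpha(m) = a0 + a1/m on informative transcripts
  use <- raw > 0 & means > 0
  if (sum(use) >= 10) {
    fit <- lm(raw[use] ~ I(1 / means[use]))
    a0 <- max(coef(fit)[1], 0); a1 <- max(coef(fit)[2], 0)
    trend <- a0 + a1 / pmax(means, .Machine$double.eps)
  } else {
    trend <- rep(if (any(use)) median(raw[use]) else 0, nrow(counts))
  }
  out <- pmax((1 - shrinkage) * raw_f + shrinkage * trend, floor)
  # uncertainty of the shrunk estimate, propagated into the Wald reference:
  # shrinking by w scales the estimator variance by (1-w)^2
  attr(out, "eff_df") <- if (shrinkage >= 1) Inf else den / (1 - shrinkage)^2
  out
}

#' Differential abundance by per-transcript NB Wald test
#'
#' Fits, per transcript, a negative binomial log-link GLM with condition as
#' the single covariate and log size factors as offset, at the supplied
#' (fixed) dispersions, and tests the condition coefficient with a Wald
#' test. Fold changes are reported as the second condition level versus the
#' first; p-values are BH-adjusted across transcripts.
#'
#' Transcripts with zero counts in every library get `base_mean = 0`,
#' `log2fc = 0`, `p_value = 1` by convention. A condition with a zero count
#' total (but not all-zero overall) is held at a pseudocount floor of 0.5
#' counts over the condition's effective depth, bounding the fold change.
#'
#' @param experiment A [count_experiment()] object.
#' @param dispersions Per-transcript dispersion vector (or scalar); computed
#'   with [estimate_dispersion()] when missing.
#' @param size_factors Optional per-library size factors.
#' @param pseudocount Floor (in counts) for empty condition totals.
#' @return A data.frame with columns `transcript_id`, `base_mean`,
#'   `log2fc`, `se_log2fc`, `p_value`, `fdr`.
#' @export
differential_abundance <- function(experiment, dispersions = NULL,
                                   size_factors = NULL, pseudocount = 0.5) {
  stopifnot(inherits(experiment, "CountExperiment"))
  counts <- experiment$counts
  cond <- experiment$condition
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(experiment)
  test_df <- attr(dispersions, "eff_df") %||% Inf
  dispersions <- rep_len(dispersions, nrow(counts))
  jA <- cond == levels(cond)[1]
  jB <- cond == levels(cond)[2]
  fA <- nb_fit_cell(counts[, jA, drop = FALSE], size_factors[jA],
                    dispersions, pseudocount)
  fB <- nb_fit_cell(counts[, jB, drop = FALSE], size_factors[jB],
                    dispersions, pseudocount)
  delta <- fB$beta - fA$beta
  se <- sqrt(1 / fA$info + 1 / fB$info)
  z <- delta / se
  p <- 2 * pt(-abs(z), df = test_df)
  base_mean <- rowMeans(sweep(counts, 2, size_factors, "/"))
  allzero <- rowSums(counts) == 0
  res <- data.frame(
    transcript_id = experiment$transcript_ids,
    base_mean = base_mean,
    log2fc = delta / log(2),
    se_log2fc = se / log(2),
    p_value = p,
    stringsAsFactors = FALSE
  )
  res$log2fc[allzero] <- 0
  res$p_value[allzero] <- 1
  res$se_log2fc[allzero] <- NA_real_
  res$fdr <- bh_fdr(res$p_value)
  res
}

#' Thresholds for the enhanced-TE classification
#'
#' Default thresholds follow the published rule: RNA abundance counts as
#' changed only when |log2 fold change| exceeds 2 (no significance
#' condition), ribosome occupancy counts as changed when the Wald p-value is
#' below 0.01 *and* |log2 fold change| exceeds 0.5.
#'
#' @param rna_abs_log2fc Positive bound on |RNA log2FC| (default 2).
#' @param ribo_abs_log2fc Positive bound on |Ribo log2FC| (default 0.5).
#' @param ribo_p Ribo p-value cutoff in (0, 1] (default 0.01).
#' @return A `TEThresholds` list.
#' @export
te_thresholds <- function(rna_abs_log2fc = 2, ribo_abs_log2fc = 0.5,
                          ribo_p = 0.01) {
  stopifnot(rna_abs_log2fc > 0, ribo_abs_log2fc > 0,
            ribo_p > 0, ribo_p <= 1)
  structure(list(rna_abs_log2fc = rna_abs_log2fc,
                 ribo_abs_log2fc = ribo_abs_log2fc,
                 ribo_p = ribo_p),
            class = "TEThresholds")
}

#' Classify transcripts by RNA abundance and ribosome occupancy status
#'
#' Joins per-transcript RNA-seq and Ribo-seq differential results and labels
#' each transcript: `rna_status` is up/down when |RNA log2FC| exceeds the
#' RNA bound (sign decides direction), unchanged otherwise;
#' `occupancy_status` is up/down when the Ribo p-value is below the cutoff
#' and |Ribo log2FC| exceeds the Ribo bound. Transcripts with *enhanced
#' translational efficiency* are exactly those unaltered in RNA-seq but
#' upregulated in Ribo-seq. Transcripts present in only one assay are
#' dropped with a message.
#'
#' @param rna,ribo Differential result data.frames from
#'   [differential_abundance()] (need `transcript_id`, `log2fc`, `p_value`).
#' @param thresholds A [te_thresholds()] object.
#' @return A data.frame with `transcript_id`, `rna_status`,
#'   `occupancy_status` (factors: up/down/unchanged), and logical
#'   `enhanced_te`.
#' @export
classify_te <- function(rna, ribo, thresholds = te_thresholds()) {
  stopifnot(inherits(thresholds, "TEThresholds"))
  common <- intersect(rna$transcript_id, ribo$transcript_id)
  dropped <- setdiff(union(rna$transcript_id, ribo$transcript_id), common)
  if (length(dropped))
    message(length(dropped), " transcript(s) present in one assay only; excluded")
  rna <- rna[match(common, rna$transcript_id), ]
  ribo <- ribo[match(common, ribo$transcript_id), ]
  lv <- c("up", "down", "unchanged")
  rna_status <- ifelse(rna$log2fc > thresholds$rna_abs_log2fc, "up",
                ifelse(rna$log2fc < -thresholds$rna_abs_log2fc, "down",
                       "unchanged"))
  occ_sig <- ribo$p_value < thresholds$ribo_p
  occupancy_status <- ifelse(
    occ_sig & ribo$log2fc > thresholds$ribo_abs_log2fc, "up",
    ifelse(occ_sig & ribo$log2fc < -thresholds$ribo_abs_log2fc, "down",
           "unchanged"))
  data.frame(
    transcript_id = common,
    rna_status = factor(rna_status, levels = lv),
    occupancy_status = factor(occupancy_status, levels = lv),
    enhanced_te = rna_status == "unchanged" & occupancy_status == "up",
    stringsAsFactors = FALSE
  )
}

#' GLM interaction test for translational efficiency change
#'
#' Fits, per transcript, the negative binomial log-link GLM on the stacked
#' RNA-seq and Ribo-seq counts with covariates condition + assay +
#' condition:assay and per-assay log size factors as offset, and Wald-tests
#' the interaction coefficient — the log2 change in translational efficiency
#' between conditions. The design is saturated in the four assay x condition
#' cell means, so the interaction estimate is
#' `(ribo log2FC) - (rna log2FC)` with variance summed over the four cells'
#' Fisher informations.
#'
#' @param rna,ribo [count_experiment()] objects sharing transcripts (same
#'   ids, same order) and the same two condition levels.
#' @param dispersions Per-transcript dispersion shared across assays;
#'   estimated from the pooled per-assay estimates when missing.
#' @param pseudocount Floor (in counts) for empty cells.
#' @param size_factors_rna,size_factors_ribo Optional per-library size
#'   factors (estimated per assay by [estimate_size_factors()] when
#'   missing).
#' @return A data.frame with `transcript_id`, `delta_te_log2`, `se`,
#'   `p_value`, `fdr`, `dispersion_used`.
#' @export
glm_te_interaction <- function(rna, ribo, dispersions = NULL,
                               pseudocount = 0.5,
                               size_factors_rna = NULL,
                               size_factors_ribo = NULL) {
  stopifnot(inherits(rna, "CountExperiment"),
            inherits(ribo, "CountExperiment"))
  if (!identical(rna$transcript_ids, ribo$transcript_ids))
    stop("RNA and Ribo experiments must share transcripts (same order)")
  if (!identical(levels(rna$condition), levels(ribo$condition)))
    stop("RNA and Ribo experiments must share condition levels")
  if (any(table(rna$condition) < 1) || any(table(ribo$condition) < 1))
    stop("degenerate design: an assay x condition cell has no libraries")
  if (is.null(dispersions)) {
    d_rna <- estimate_dispersion(rna)
    d_ribo <- estimate_dispersion(ribo)
    dispersions <- (d_rna + d_ribo) / 2
    # averaging two independent estimates doubles the effective df
    attr(dispersions, "eff_df") <- (attr(d_rna, "eff_df") %||% Inf) +
      (attr(d_ribo, "eff_df") %||% Inf)
  }
  test_df <- attr(dispersions, "eff_df") %||% Inf
  dispersions <- rep_len(dispersions, nrow(rna$counts))
  fit_assay <- function(exp, sf) {
    if (is.null(sf)) sf <- estimate_size_factors(exp$counts)
    cond <- exp$condition
    lapply(levels(cond), function(lev) {
      j <- cond == lev
      nb_fit_cell(exp$counts[, j, drop = FALSE], sf[j], dispersions,
                  pseudocount)
    })
  }
  frna <- fit_assay(rna, size_factors_rna)
  fribo <- fit_assay(ribo, size_factors_ribo)
  delta <- (fribo[[2]]$beta - fribo[[1]]$beta) -
           (frna[[2]]$beta - frna[[1]]$beta)
  v <- 1 / frna[[1]]$info + 1 / frna[[2]]$info +
       1 / fribo[[1]]$info + 1 / fribo[[2]]$info
  z <- delta / sqrt(v)
  p <- 2 * pt(-abs(z), df = test_df)
  allzero <- rowSums(rna$counts) + rowSums(ribo$counts) == 0
  res <- data.frame(
    transcript_id = rna$transcript_ids,
    delta_te_log2 = delta / log(2),
    se = sqrt(v) / log(2),
    p_value = p,
    dispersion_used = dispersions,
    stringsAsFactors = FALSE
  )
  res$delta_te_log2[allzero] <- 0
  res$p_value[allzero] <- 1
  res$fdr <- bh_fdr(res$p_value)
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment across a p-value vector; a thin,
#' documented wrapper over [stats::p.adjust()] with `method = "BH"` so that
#' every multiple-testing correction in the package goes through one
#' auditable entry point.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Low-count filter for GLM testing
#'
#' Flags transcripts whose size-factor-normalized mean count is below
#' `min_norm_mean` in *both* assays; such transcripts are excluded from
#' testing for GLM stability and reported as filtered.
#'
#' @param rna,ribo [count_experiment()] objects sharing transcripts.
#' @param min_norm_mean Normalized-mean cutoff (default 1).
#' @return Logical vector, TRUE = keep.
#' @export
filter_low_counts <- function(rna, ribo, min_norm_mean = 1) {
  m_rna <- rowMeans(sweep(rna$counts, 2, estimate_size_factors(rna$counts), "/"))
  m_ribo <- rowMeans(sweep(ribo$counts, 2, estimate_size_factors(ribo$counts), "/"))
  m_rna >= min_norm_mean | m_ribo >= min_norm_mean
}
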