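# Synthetic data generators.
#
# The generators emulate a two-condition (empty-vector vs NSUN5-restored)
# sequencing study: replicated NB counts for paired RNA-seq/Ribo-seq with a
# small transcriptionally-DE fraction and a larger ribosome-occupancy
# shifted fraction (a planted enhanced-TE program), bisulfite pileups with
# one planted high-methylation cytosine on a low-methylation background
# with imperfect conversion, and bisulfite amplicon clone sequences.
# Every generator returns ground truth for recovery testing.

#' Configuration for the paired RNA-seq/Ribo-seq simulation
#'
#' Defaults describe the simulated study conditions: ~2% of transcripts
#' transcriptionally DE (mirroring the small changed fraction of the real
#' screen), 8% with a ribosome-occupancy-only shift of +1 log2 unit (the
#' planted enhanced-TE program), dispersion 0.1, and 3 replicates per
#' condition.
#'
#' @param n_transcripts Number of transcripts.
#' @param n_reps_per_condition Replicate libraries per condition per assay.
#' @param baseline_log2_mean,baseline_log2_sd Log2-normal parameters of the
#'   per-transcript baseline expression (per kb of length).
#' @param length_range_bp Length range; lengths are drawn log-uniformly and
#'   expected counts scale linearly with length.
#' @param dispersion NB dispersion alpha (scalar or per-transcript);
#'   `0` gives Poisson counts.
#' @param lib_size_range Library sizes are drawn uniformly in this range and
#'   enter only through size factors (library / geometric mean).
#' @param frac_rna_de Fraction of transcripts shifted in *both* assays by
#'   `rna_de_log2fc` (split evenly up/down).
#' @param rna_de_log2fc Magnitude of the transcriptional shift (log2).
#' @param frac_te_up Fraction shifted in Ribo-seq only by `te_log2fc`.
#' @param te_log2fc Ribosome-occupancy shift (log2) of the planted TE set.
#' @param seed Integer RNG seed.
#' @return A `TESimConfig` list.
#' @export
te_sim_config <- function(n_transcripts = 2000, n_reps_per_condition = 3,
                          baseline_log2_mean = 5, baseline_log2_sd = 2,
                          length_range_bp = c(200L, 10000L),
                          dispersion = 0.1,
                          lib_size_range = c(8e5, 1.2e6),
                          frac_rna_de = 0.02, rna_de_log2fc = 3,
                          frac_te_up = 0.08, te_log2fc = 1,
                          seed = 1L) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              n_reps_per_condition = as.integer(n_reps_per_condition),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              length_range_bp = length_range_bp,
              dispersion = dispersion,
              lib_size_range = lib_size_range,
              frac_rna_de = frac_rna_de, rna_de_log2fc = rna_de_log2fc,
              frac_te_up = frac_te_up, te_log2fc = te_log2fc,
              seed = as.integer(seed))
  stopifnot(cfg$n_transcripts >= 1, cfg$n_reps_per_condition >= 1,
            cfg$baseline_log2_sd >= 0, all(cfg$length_range_bp >= 1),
            all(cfg$dispersion >= 0), all(cfg$lib_size_range > 0),
            cfg$frac_rna_de >= 0, cfg$frac_rna_de <= 1,
            cfg$frac_te_up >= 0, cfg$frac_te_up <= 1)
  if (cfg$frac_rna_de + cfg$frac_te_up > 1)
    stop("frac_rna_de + frac_te_up must not exceed 1 (disjoint planted sets)")
  structure(cfg, class = "TESimConfig")
}

.rcounts <- function(n, mu, alpha) {
  # NB with var = mu + alpha mu^2; alpha = 0 degenerates to Poisson
  if (length(alpha) == 1 && alpha == 0) return(rpois(n, mu))
  alpha <- rep_len(alpha, n)
  out <- integer(n)
  pois <- alpha == 0
  if (any(pois)) out[pois] <- rpois(sum(pois), rep_len(mu, n)[pois])
  if (any(!pois)) out[!pois] <- rnbinom(sum(!pois),
                                        mu = rep_len(mu, n)[!pois],
                                        size = 1 / alpha[!pois])
  out
}

#' Simulate a paired RNA-seq/Ribo-seq experiment with ground truth
#'
#' Counts are NB with mean `size_factor * baseline * 2^(condition effect)`.
#' Planted sets are chosen deterministically: after a seeded shuffle of the
#' transcript ids, the first `floor(frac_rna_de * n)` become `rna_de`
#' (shifting both assays; alternating up/down) and the next
#' `floor(frac_te_up * n)` become `te_up` (shifting Ribo-seq only, by
#' `te_log2fc`, in the second condition "NSUN5"). Library sizes are drawn
#' once, uniformly in `lib_size_range`, separately per assay.
#'
#' @param config A [te_sim_config()] object.
#' @return A list with elements `rna` and `ribo` ([count_experiment()]
#'   objects sharing transcripts and lengths) and `truth`, a data.frame with
#'   `transcript_id`, `true_rna_log2fc`, `true_te_log2fc`, `planted_class`
#'   (factor: null / rna_de / te_up).
#' @export
simulate_te_experiment <- function(config = te_sim_config()) {
  stopifnot(inherits(config, "TESimConfig"))
  set.seed(config$seed)
  n <- config$n_transcripts
  nr <- config$n_reps_per_condition
  ids <- sprintf("tx%05d", seq_len(n))
  lengths <- round(exp(runif(n, log(config$length_range_bp[1]),
                             log(config$length_range_bp[2]))))
  q <- 2^rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd) *
    (lengths / 1000)

  k_de <- floor(config$frac_rna_de * n)
  k_te <- floor(config$frac_te_up * n)
  shuffled <- sample.int(n)
  idx_de <- shuffled[seq_len(k_de)]
  idx_te <- shuffled[k_de + seq_len(k_te)]
  rna_fc <- numeric(n)
  if (k_de > 0)
    rna_fc[idx_de] <- config$rna_de_log2fc *
      rep_len(c(1, -1), k_de)   # alternate up/down
  te_fc <- numeric(n)
  te_fc[idx_te] <- config$te_log2fc
  planted <- rep("null", n)
  planted[idx_de] <- "rna_de"
  planted[idx_te] <- "te_up"

  condition <- factor(rep(c("EV", "NSUN5"), each = nr),
                      levels = c("EV", "NSUN5"))
  is_b <- as.integer(condition == "NSUN5")
  make_assay <- function(extra_fc, assay) {
    libsize <- runif(2 * nr, config$lib_size_range[1],
                     config$lib_size_range[2])
    sf <- libsize / exp(mean(log(libsize)))
    mu <- outer(q, sf) * 2^(outer(rna_fc + extra_fc, is_b))
    cnt <- matrix(.rcounts(length(mu), as.vector(mu),
                           rep(rep_len(config$dispersion, n), 2 * nr)),
                  nrow = n)
    dimnames(cnt) <- list(ids, paste0(assay, "_", condition, "_",
                                      rep(seq_len(nr), 2)))
    count_experiment(cnt, lengths, condition, assay = assay)
  }
  rna <- make_assay(0, "rna")
  ribo <- make_assay(te_fc, "ribo")
  truth <- data.frame(
    transcript_id = ids,
    true_rna_log2fc = rna_fc,
    true_te_log2fc = te_fc,
    planted_class = factor(planted, levels = c("null", "rna_de", "te_up")),
    stringsAsFactors = FALSE
  )
  list(rna = rna, ribo = ribo, truth = truth)
}

#' Configuration for the bisulfite RNA-seq pileup simulation
#'
#' Defaults emulate the rRNA bisulfite screen: 1000 cytosine sites at 2%
#' background methylation, one planted site (a stand-in for 28S C3782) at
#' 95% methylation in the "NSUN5" condition versus 5% in "EV", Poisson
#' coverage around 100x, and a 1% bisulfite conversion failure rate that
#' inflates apparent methylation.
#'
#' @param n_sites Number of cytosine sites (1-based coordinates 1..n).
#' @param n_reps_per_condition Libraries per condition.
#' @param coverage_mean Poisson mean coverage per site and library.
#' @param background_methylation True methylation at non-planted sites.
#' @param planted_site_index 1-based index of the planted site; defaults
#'   to 378 (an arbitrary echo of the rRNA coordinate convention) or the
#'   middle site when `n_sites` is smaller.
#' @param planted_methylation_by_condition Length-2 proportions, true
#'   methylation of the planted site in conditions ("EV", "NSUN5").
#' @param conversion_failure_rate Probability an unmethylated C escapes
#'   conversion and reads as methylated.
#' @param seed Integer RNG seed.
#' @return A `BsSimConfig` list.
#' @export
bs_sim_config <- function(n_sites = 1000, n_reps_per_condition = 3,
                          coverage_mean = 100,
                          background_methylation = 0.02,
                          planted_site_index = NULL,
                          planted_methylation_by_condition = c(EV = 0.05,
                                                               NSUN5 = 0.95),
                          conversion_failure_rate = 0.01,
                          seed = 1L) {
  if (is.null(planted_site_index))
    planted_site_index <- if (n_sites >= 378) 378L else ceiling(n_sites / 2)
  cfg <- list(n_sites = as.integer(n_sites),
              n_reps_per_condition = as.integer(n_reps_per_condition),
              coverage_mean = coverage_mean,
              background_methylation = background_methylation,
              planted_site_index = as.integer(planted_site_index),
              planted_methylation_by_condition =
                planted_methylation_by_condition,
              conversion_failure_rate = conversion_failure_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_sites >= 1, cfg$n_reps_per_condition >= 1,
            cfg$coverage_mean > 0,
            cfg$background_methylation >= 0, cfg$background_methylation <= 1,
            length(cfg$planted_methylation_by_condition) == 2,
            all(cfg$planted_methylation_by_condition >= 0),
            all(cfg$planted_methylation_by_condition <= 1),
            cfg$conversion_failure_rate >= 0,
            cfg$conversion_failure_rate <= 1)
  if (cfg$planted_site_index < 1 || cfg$planted_site_index > cfg$n_sites)
    stop("planted_site_index out of range 1..n_sites")
  structure(cfg, class = "BsSimConfig")
}

#' Simulate a bisulfite RNA-seq pileup
#'
#' One row per site x library. Coverage is Poisson(`coverage_mean`); the
#' unconverted count is Binomial(coverage, `m + (1 - m) * cf`) where `m` is
#' the site's true methylation (condition-specific at the planted site,
#' `background_methylation` elsewhere) and `cf` the conversion failure
#' rate.
#'
#' @param config A [bs_sim_config()] object.
#' @return A data.frame (class `BisulfitePileup`) with columns `site`
#'   (1-based), `library`, `condition`, `coverage`, `unconverted`, plus a
#'   `truth` attribute giving the per-site, per-condition true methylation.
#' @export
simulate_bsrna_pileup <- function(config = bs_sim_config()) {
  stopifnot(inherits(config, "BsSimConfig"))
  set.seed(config$seed)
  ns <- config$n_sites; nr <- config$n_reps_per_condition
  conds <- c("EV", "NSUN5")
  m_true <- matrix(config$background_methylation, nrow = ns, ncol = 2,
                   dimnames = list(NULL, conds))
  m_true[config$planted_site_index, ] <-
    config$planted_methylation_by_condition
  rows <- vector("list", 2 * nr)
  k <- 0
  for (ci in 1:2) {
    p_obs <- m_true[, ci] + (1 - m_true[, ci]) * config$conversion_failure_rate
    for (r in seq_len(nr)) {
      cov <- rpois(ns, config$coverage_mean)
      unc <- rbinom(ns, cov, p_obs)
      k <- k + 1
      rows[[k]] <- data.frame(
        site = seq_len(ns),
        library = paste0("bs_", conds[ci], "_", r),
        condition = conds[ci],
        coverage = cov,
        unconverted = unc,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$condition <- factor(out$condition, levels = conds)
  class(out) <- c("BisulfitePileup", "data.frame")
  attr(out, "truth") <- data.frame(site = seq_len(ns),
                                   m_EV = m_true[, 1], m_NSUN5 = m_true[, 2])
  out
}

#' Configuration for the bisulfite clone simulation
#'
#' @param amplicon_sequence Reference amplicon (A/C/G/T/U/N; U treated
#'   as T).
#' @param cytosine_mode `"all_c"` (every cytosine is a queried site; RNA
#'   bisulfite) or `"cpg_only"` (only CpG cytosines queried; non-CpG Cs are
#'   always written converted).
#' @param n_clones Number of clone sequences (the study design sequenced a
#'   minimum of eight per sample).
#' @param per_site_methylation Methylation probability per queried cytosine
#'   (recycled if scalar).
#' @param sequencing_error_rate Per-base probability of a random substitution
#'   applied after conversion.
#' @param seed Integer RNG seed.
#' @return A `CloneSimConfig` list.
#' @export
clone_sim_config <- function(amplicon_sequence, cytosine_mode = "all_c",
                             n_clones = 8, per_site_methylation = 0.5,
                             sequencing_error_rate = 0, seed = 1L) {
  amplicon_sequence <- normalize_sequence(amplicon_sequence)
  cytosine_mode <- match.arg(cytosine_mode, c("all_c", "cpg_only"))
  qpos <- queried_cytosines(amplicon_sequence, cytosine_mode)
  if (length(qpos) == 0)
    stop("amplicon contains no queried cytosine under mode '",
         cytosine_mode, "'")
  if (!length(per_site_methylation) %in% c(1L, length(qpos)))
    stop("per_site_methylation must be scalar or one value per queried ",
         "cytosine (", length(qpos), ")")
  per_site_methylation <- rep_len(per_site_methylation, length(qpos))
  stopifnot(n_clones >= 1, all(per_site_methylation >= 0),
            all(per_site_methylation <= 1),
            sequencing_error_rate >= 0, sequencing_error_rate <= 1)
  structure(list(amplicon_sequence = amplicon_sequence,
                 cytosine_mode = cytosine_mode,
                 n_clones = as.integer(n_clones),
                 per_site_methylation = per_site_methylation,
                 sequencing_error_rate = sequencing_error_rate,
                 seed = as.integer(seed)),
            class = "CloneSimConfig")
}

#' Simulate bisulfite-converted clone sequences
#'
#' For each clone, every queried cytosine is methylated with its
#' `per_site_methylation` probability: methylated cytosines resist
#' conversion and are written `C`, unmethylated ones are written `T`.
#' Non-queried cytosines are always written `T` (fully converted). A
#' uniform random substitution is then applied per base at the sequencing
#' error rate.
#'
#' @param config A [clone_sim_config()] object.
#' @return A list with `clones` (named character vector of sequences),
#'   `positions` (1-based queried cytosine coordinates), and `truth`
#'   (data.frame of per-position Bernoulli means).
#' @export
simulate_clones <- function(config) {
  stopifnot(inherits(config, "CloneSimConfig"))
  set.seed(config$seed)
  ref <- strsplit(config$amplicon_sequence, "")[[1]]
  qpos <- queried_cytosines(config$amplicon_sequence, config$cytosine_mode)
  base <- ref
  base[base == "C"] <- "T"   # full conversion background
  clones <- vapply(seq_len(config$n_clones), function(i) {
    s <- base
    meth <- runif(length(qpos)) < config$per_site_methylation
    s[qpos[meth]] <- "C"
    if (config$sequencing_error_rate > 0) {
      err <- which(runif(length(s)) < config$sequencing_error_rate)
      for (j in err)
        s[j] <- sample(setdiff(c("A", "C", "G", "T"), s[j]), 1)
    }
    paste(s, collapse = "")
  }, character(1))
  names(clones) <- sprintf("clone%02d", seq_len(config$n_clones))
  list(clones = clones,
       positions = qpos,
       truth = data.frame(position = qpos,
                          methylation = config$per_site_methylation))
}
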