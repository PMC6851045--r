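# End-to-end pipeline driver: simulate (optional) -> TE analysis ->
# enrichment and/or bisulfite methylation, with a single global seed fanned
# out per stage (stage_seed = seed + 1000 * stage_index) so individual
# stages stay reproducible when toggled.

.pipeline_stages <- c("simulate", "te", "bsrna", "clones", "enrich")

#' Default demonstration pipeline configuration
#'
#' A complete run on synthetic data: paired RNA/Ribo counts with planted
#' transcriptional and translational programs, a bisulfite pileup with one
#' planted high-methylation site, eight bisulfite clones of a random
#' amplicon (one highly methylated cytosine on a low background), and a
#' demo GMT collection containing the planted TE program among random
#' sets.
#'
#' @param outdir Output directory.
#' @param seed Global seed.
#' @return A `RunConfig` list accepted by [run_pipeline()].
#' @export
demo_config <- function(outdir = tempfile("riboshift_run_"), seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, te = TRUE, bsrna = TRUE,
                  clones = TRUE, enrich = TRUE),
    simulate = list(
      te = list(n_transcripts = 2000),
      bsrna = list(),
      clones = list(n_clones = 8),
      n_random_gene_sets = 10,
      random_set_size = 50
    ),
    te = list(
      thresholds = list(rna_abs_log2fc = 2, ribo_abs_log2fc = 0.5,
                        ribo_p = 0.01),
      deficient_arm = "NSUN5",
      pseudocount = 0.5,
      min_norm_mean = 1,
      shrinkage = 0.5
    ),
    bsrna = list(condition = "NSUN5", threshold = 0.9, min_coverage = 30,
                 control_sites = NULL),
    clones = list(mode = "all_c", min_clones = 8),
    enrich = list(fdr = 0.05, min_size = 5, max_size = 2000)
  )
}

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
  x
}

# random amplicon with one high-methylation cytosine for the clone demo
.demo_amplicon <- function(seed, length_bp = 120) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE,
               prob = c(0.3, 0.2, 0.3, 0.2)), collapse = "")
}

#' Run the analysis pipeline
#'
#' Composes the stages selected in `config$stages`; see [demo_config()] for
#' the configuration layout. When the simulate stage is off, the `te`,
#' `bsrna` and `clones` sections must carry input file paths
#' (`rna_counts`/`ribo_counts`/`lengths`/`design`, `pileup`,
#' `clones_fasta`/`reference_fasta`) and `enrich` a `gmt` path. All outputs
#' are TSV/FASTA/JSON under `config$outdir`; the returned summary is also
#' written to `summary.json`. Given the same config and seed the run is
#' byte-reproducible.
#'
#' @param config A `RunConfig` list or path to a YAML file with the same
#'   structure.
#' @return The run summary (invisibly a list), with per-stage parameters,
#'   class counts, called sites and enriched sets.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .check_keys(config, c("outdir", "seed", "stages",
                                  .pipeline_stages), "config")
  stages <- .check_keys(config$stages %||% list(), .pipeline_stages,
                        "stages")
  stages <- lapply(setNames(.pipeline_stages, .pipeline_stages),
                   function(s) isTRUE(stages[[s]]))
  outdir <- config$outdir %||% stop("config$outdir is required")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(outdir, ...)
  summary <- list(package = "riboshift",
                  version = as.character(utils::packageVersion("riboshift")),
                  seed = seed,
                  stages_run = names(Filter(identity, stages)))
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  files <- list()
  if (stages$simulate) run_stage("simulate", function() {
    sim <- config$simulate %||% list()
    .check_keys(sim, c("te", "bsrna", "clones", "n_random_gene_sets",
                       "random_set_size"), "simulate")
    te_cfg <- do.call(te_sim_config,
                      c(sim$te %||% list(), list(seed = seed + 1000L)))
    bs_cfg <- do.call(bs_sim_config,
                      c(sim$bsrna %||% list(), list(seed = seed + 2000L)))
    cl_args <- sim$clones %||% list()
    if (is.null(cl_args$amplicon_sequence)) {
      amp <- .demo_amplicon(seed + 3000L)
      nq <- length(queried_cytosines(amp, cl_args$cytosine_mode %||% "all_c"))
      m <- rep(0.05, nq)
      m[ceiling(nq / 2)] <- 0.9     # one high-methylation cytosine
      cl_args$amplicon_sequence <- amp
      if (is.null(cl_args$per_site_methylation))
        cl_args$per_site_methylation <- m
    }
    cl_cfg <- do.call(clone_sim_config,
                      c(cl_args, list(seed = seed + 3001L)))
    te_sim <- simulate_te_experiment(te_cfg)
    pile <- simulate_bsrna_pileup(bs_cfg)
    clones <- simulate_clones(cl_cfg)

    write_count_experiment(te_sim$rna, pth("rna_counts.tsv"),
                           pth("lengths.tsv"), pth("design.tsv"))
    write_count_experiment(te_sim$ribo, pth("ribo_counts.tsv"),
                           design_path = pth("design.tsv"),
                           append_design = TRUE)
    write_tsv(te_sim$truth, pth("te_truth.tsv"),
              comments = list(seed = te_cfg$seed))
    write_pileup(pile, pth("bsrna_pileup.tsv"))
    write_tsv(attr(pile, "truth"), pth("bsrna_truth.tsv"))
    write_fasta(clones$clones, pth("clones.fasta"))
    write_fasta(c(amplicon = cl_cfg$amplicon_sequence),
                pth("amplicon.fasta"))
    write_tsv(clones$truth, pth("clone_truth.tsv"))

    # demo GMT: the planted TE program among random sets
    set.seed(seed + 4000L)
    ids <- te_sim$truth$transcript_id
    te_ids <- ids[te_sim$truth$planted_class == "te_up"]
    nrand <- sim$n_random_gene_sets %||% 10
    rsz <- sim$random_set_size %||% 50
    gmt <- c(
      sprintf("PLANTED_TE_PROGRAM\tplanted\t%s",
              paste(te_ids, collapse = "\t")),
      vapply(seq_len(nrand), function(i)
        sprintf("RANDOM_SET_%02d\trandom\t%s", i,
                paste(sample(ids, rsz), collapse = "\t")), character(1)))
    writeLines(gmt, pth("gene_sets.gmt"))
    files$simulate <<- c("rna_counts.tsv", "ribo_counts.tsv", "lengths.tsv",
                         "design.tsv", "te_truth.tsv", "bsrna_pileup.tsv",
                         "bsrna_truth.tsv", "clones.fasta", "amplicon.fasta",
                         "clone_truth.tsv", "gene_sets.gmt")
    summary$simulate <<- list(
      te_config = unclass(te_cfg)[c("n_transcripts", "n_reps_per_condition",
                                    "dispersion", "frac_rna_de",
                                    "frac_te_up", "te_log2fc", "seed")],
      bsrna_seed = bs_cfg$seed, clones_seed = cl_cfg$seed)
  })

  class_df <- NULL
  tested_ids <- NULL
  if (stages$te) run_stage("te", function() {
    tecfg <- .check_keys(config$te %||% list(),
                         c("thresholds", "deficient_arm", "pseudocount",
                           "min_norm_mean", "shrinkage", "rna_counts",
                           "ribo_counts", "lengths", "design"), "te")
    rna <- read_count_experiment(tecfg$rna_counts %||% pth("rna_counts.tsv"),
                                 tecfg$lengths %||% pth("lengths.tsv"),
                                 tecfg$design %||% pth("design.tsv"), "rna")
    ribo <- read_count_experiment(tecfg$ribo_counts %||% pth("ribo_counts.tsv"),
                                  tecfg$lengths %||% pth("lengths.tsv"),
                                  tecfg$design %||% pth("design.tsv"), "ribo")
    keep <- filter_low_counts(rna, ribo, tecfg$min_norm_mean %||% 1)
    rna_f <- subset_experiment(rna, keep)
    ribo_f <- subset_experiment(ribo, keep)
    shr <- tecfg$shrinkage %||% 0.5
    pc <- tecfg$pseudocount %||% 0.5
    d_rna <- estimate_dispersion(rna_f, shrinkage = shr)
    d_ribo <- estimate_dispersion(ribo_f, shrinkage = shr)
    res_rna <- differential_abundance(rna_f, d_rna, pseudocount = pc)
    res_ribo <- differential_abundance(ribo_f, d_ribo, pseudocount = pc)
    thr <- do.call(te_thresholds, tecfg$thresholds %||% list())
    cls <- classify_te(res_rna, res_ribo, thr)
    arm <- tecfg$deficient_arm %||% levels(rna$condition)[2]
    if (!arm %in% levels(rna$condition))
      stop("deficient_arm '", arm, "' is not a condition level")
    if (arm == levels(rna$condition)[1]) {
      # program reported for the reference arm: occupancy "down" vs the
      # comparison arm means "up" in the deficient arm
      cls$enhanced_te <- cls$rna_status == "unchanged" &
        cls$occupancy_status == "down"
    }
    d_avg <- (d_rna + d_ribo) / 2
    attr(d_avg, "eff_df") <- (attr(d_rna, "eff_df") %||% Inf) +
      (attr(d_ribo, "eff_df") %||% Inf)
    inter <- glm_te_interaction(rna_f, ribo_f, d_avg, pseudocount = pc)
    # per-library TE values and per-condition means
    sf_rna <- estimate_size_factors(rna_f$counts)
    sf_ribo <- estimate_size_factors(ribo_f$counts)
    te_mat <- compute_te(rpkm(rna_f$counts, rna_f$lengths_bp, sf_rna),
                         rpkm(ribo_f$counts, ribo_f$lengths_bp, sf_ribo),
                         pseudocount = pc)
    write_tsv(res_rna, pth("rna_differential.tsv"),
              comments = list(contrast = paste(levels(rna$condition)[2],
                                               "vs",
                                               levels(rna$condition)[1])))
    write_tsv(res_ribo, pth("ribo_differential.tsv"))
    write_tsv(cls, pth("te_classification.tsv"),
              comments = list(rna_abs_log2fc = thr$rna_abs_log2fc,
                              ribo_abs_log2fc = thr$ribo_abs_log2fc,
                              ribo_p = thr$ribo_p, deficient_arm = arm))
    write_tsv(inter, pth("te_interaction.tsv"))
    write_tsv(data.frame(transcript_id = rna_f$transcript_ids,
                         round(te_mat, 6), check.names = FALSE),
              pth("te_values.tsv"))
    class_df <<- cls
    tested_ids <<- rna_f$transcript_ids
    summary$te <<- list(
      thresholds = unclass(thr), deficient_arm = arm,
      n_tested = length(tested_ids),
      n_filtered_low_count = sum(!keep),
      class_counts = list(
        rna = as.list(table(cls$rna_status)),
        occupancy = as.list(table(cls$occupancy_status)),
        enhanced_te = sum(cls$enhanced_te)))
  })

  if (stages$bsrna) run_stage("bsrna", function() {
    bcfg <- .check_keys(config$bsrna %||% list(),
                        c("condition", "threshold", "min_coverage",
                          "control_sites", "pileup"), "bsrna")
    pile <- read_pileup(bcfg$pileup %||% pth("bsrna_pileup.tsv"))
    eff <- if (!is.null(bcfg$control_sites))
      estimate_conversion_efficiency(pile, bcfg$control_sites) else 1
    cond <- bcfg$condition %||% levels(pile$condition)[2]
    hits <- call_high_methylation_sites(pile, cond,
                                        threshold = bcfg$threshold %||% 0.9,
                                        min_coverage = bcfg$min_coverage %||% 30,
                                        efficiency = eff)
    lv <- pileup_level_matrices(pile, efficiency = eff)
    tst <- moderated_t_site_test(lv$levels_A, lv$levels_B, sites = lv$sites)
    write_tsv(hits, pth("high_methylation_sites.tsv"),
              comments = list(condition = cond, coordinates = "1-based",
                              conversion_efficiency = round(eff, 6)))
    write_tsv(tst, pth("site_moderated_t.tsv"),
              comments = list(coordinates = "1-based"))
    summary$bsrna <<- list(condition = cond,
                           conversion_efficiency = eff,
                           n_sites_called = nrow(hits),
                           called_sites = hits$site,
                           top_site_p = if (nrow(tst))
                             min(tst$p_value, na.rm = TRUE) else NULL)
  })

  if (stages$clones) run_stage("clones", function() {
    ccfg <- .check_keys(config$clones %||% list(),
                        c("mode", "min_clones", "clones_fasta",
                          "reference_fasta"), "clones")
    clones <- read_fasta(ccfg$clones_fasta %||% pth("clones.fasta"))
    ref <- read_fasta(ccfg$reference_fasta %||% pth("amplicon.fasta"))[1]
    cm <- clone_analysis(clones, ref, mode = ccfg$mode %||% "all_c",
                         min_clones = ccfg$min_clones %||% 8)
    write_tsv(data.frame(position = cm$positions,
                         frequency = cm$per_position_frequency),
              pth("clone_frequencies.tsv"),
              comments = list(coordinates = "1-based", mode = cm$mode))
    writeLines(render_lollipop(cm), pth("clone_lollipop.txt"))
    summary$clones <<- list(n_clones = length(cm$clone_ids),
                            n_positions = length(cm$positions),
                            mean_frequency =
                              mean(cm$per_position_frequency, na.rm = TRUE))
  })

  if (stages$enrich) run_stage("enrich", function() {
    ecfg <- .check_keys(config$enrich %||% list(),
                        c("gmt", "fdr", "min_size", "max_size"), "enrich")
    if (is.null(class_df)) {
      cls_path <- pth("te_classification.tsv")
      if (!file.exists(cls_path))
        stop("enrichment needs the te stage output (te_classification.tsv)")
      class_df <- read_tsv(cls_path)
      tested_ids <- class_df$transcript_id
    }
    collection <- read_gmt(ecfg$gmt %||% pth("gene_sets.gmt"))
    query <- class_df$transcript_id[class_df$enhanced_te]
    res <- hypergeometric_enrichment(query, collection, tested_ids,
                                     min_size = ecfg$min_size %||% 5,
                                     max_size = ecfg$max_size %||% 2000)
    cutoff <- ecfg$fdr %||% 0.05
    write_tsv(res, pth("enrichment.tsv"),
              comments = list(fdr_cutoff = cutoff,
                              query_size = length(query)))
    summary$enrich <<- list(
      n_sets_tested = nrow(res),
      significant_sets = res$set_name[res$fdr < cutoff],
      query_size = length(query))
  })

  summary$outputs <- sort(list.files(outdir))
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}

#' Subset a CountExperiment by transcript
#'
#' @param experiment A [count_experiment()] object.
#' @param keep Logical or index vector over transcripts.
#' @return A [count_experiment()] with the selected transcripts.
#' @export
subset_experiment <- function(experiment, keep) {
  count_experiment(experiment$counts[keep, , drop = FALSE],
                   experiment$lengths_bp[keep],
                   experiment$condition,
                   assay = experiment$assay)
}

#' Validate a pipeline run summary
#'
#' Checks that the summary produced by [run_pipeline()] carries the
#' required fields for the stages it ran.
#'
#' @param summary A summary list (or path to `summary.json`).
#' @return TRUE invisibly; errors describe the first violated field.
#' @export
validate_summary <- function(summary) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  for (f in c("package", "version", "seed", "stages_run", "outputs"))
    if (is.null(summary[[f]])) stop("summary missing field '", f, "'")
  for (s in summary$stages_run)
    if (s != "simulate" && is.null(summary[[s]]))
      stop("summary missing stage section '", s, "'")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
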