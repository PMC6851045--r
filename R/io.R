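# Plain-text I/O. All tables are TSV; comment header lines starting with
# "# " record parameters. Site coordinates in all files are 1-based.

#' Write a table as TSV with optional comment header
#'
#' @param x data.frame.
#' @param path Output path.
#' @param comments Optional named list written as `# key: value` lines.
#' @export
write_tsv <- function(x, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(sprintf("# %s: %s", names(comments),
                       vapply(comments, function(v)
                         paste(format(v), collapse = ","), character(1))),
               con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return data.frame (comment lines skipped).
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a CountExperiment to TSV files
#'
#' Writes the count matrix (rows = transcripts, columns = libraries, first
#' column `transcript_id`), a companion lengths table, and appends the
#' libraries to a design table (`library`, `assay`, `condition`).
#'
#' @param experiment A [count_experiment()] object.
#' @param counts_path,lengths_path,design_path Output paths; `lengths_path`
#'   and `design_path` may be NULL to skip.
#' @param append_design Append to an existing design file instead of
#'   overwriting.
#' @export
write_count_experiment <- function(experiment, counts_path,
                                   lengths_path = NULL, design_path = NULL,
                                   append_design = FALSE) {
  df <- data.frame(transcript_id = experiment$transcript_ids,
                   experiment$counts, check.names = FALSE)
  write_tsv(df, counts_path)
  if (!is.null(lengths_path))
    write_tsv(data.frame(transcript_id = experiment$transcript_ids,
                         length_bp = experiment$lengths_bp), lengths_path)
  if (!is.null(design_path)) {
    design <- data.frame(library = experiment$library_labels,
                         assay = experiment$assay,
                         condition = as.character(experiment$condition))
    if (append_design && file.exists(design_path)) {
      old <- read_tsv(design_path)
      design <- rbind(old, design)
    }
    write_tsv(design, design_path)
  }
  invisible(experiment)
}

#' Read a CountExperiment from TSV files
#'
#' @param counts_path Counts TSV (first column `transcript_id`).
#' @param lengths_path Lengths TSV (`transcript_id`, `length_bp`).
#' @param design_path Design TSV (`library`, `assay`, `condition`).
#' @param assay Assay whose libraries to select from the design.
#' @return A [count_experiment()] object.
#' @export
read_count_experiment <- function(counts_path, lengths_path, design_path,
                                  assay) {
  cnt <- read_tsv(counts_path)
  len <- read_tsv(lengths_path)
  design <- read_tsv(design_path)
  design <- design[design$assay == assay, , drop = FALSE]
  if (nrow(design) == 0) stop("no '", assay, "' libraries in design")
  m <- as.matrix(cnt[, design$library, drop = FALSE])
  rownames(m) <- cnt$transcript_id
  count_experiment(m,
                   lengths_bp = len$length_bp[match(cnt$transcript_id,
                                                    len$transcript_id)],
                   condition = design$condition,
                   assay = assay)
}

#' Write / read a bisulfite pileup TSV
#'
#' Columns: `site` (1-based), `library`, `condition`, `coverage`,
#' `unconverted`.
#' @param pileup Pileup data.frame.
#' @param path File path.
#' @export
write_pileup <- function(pileup, path) {
  write_tsv(as.data.frame(pileup),
            path, comments = list(coordinates = "1-based"))
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  out <- read_tsv(path)
  out$condition <- factor(out$condition)
  class(out) <- c("BisulfitePileup", "data.frame")
  out
}

#' Write / read sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path File path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
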