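#' Construct a CountExperiment
#'
#' A `CountExperiment` holds per-transcript integer counts for one assay
#' (RNA-seq or Ribo-seq) across labelled replicate libraries, together with
#' transcript lengths and a two-level condition factor assigning each
#' library to an experimental arm.
#'
#' @param counts Non-negative integer matrix, transcripts in rows and
#'   libraries in columns. Row names (or `transcript_ids`) identify
#'   transcripts; column names (or `library_labels`) identify libraries.
#' @param lengths_bp Positive integer vector of transcript lengths in bp,
#'   one per row of `counts`.
#' @param condition Factor (or coercible) with exactly two levels giving the
#'   condition of each library. The *second* level is the comparison arm:
#'   fold changes are reported as level 2 vs level 1.
#' @param transcript_ids,library_labels Optional identifier vectors,
#'   defaulting to the dimnames of `counts`.
#' @param assay Assay label, e.g. `"rna"` or `"ribo"`.
#'
#' @return An object of class `CountExperiment`: a list with elements
#'   `counts`, `lengths_bp`, `condition`, `transcript_ids`,
#'   `library_labels`, `assay`.
#' @examples
#' cnt <- matrix(rpois(40, 50), nrow = 10,
#'               dimnames = list(paste0("tx", 1:10), paste0("lib", 1:4)))
#' ce <- count_experiment(cnt, lengths_bp = rep(1000L, 10),
#'                        condition = c("EV", "EV", "NSUN5", "NSUN5"))
#' ce
#' @export
count_experiment <- function(counts, lengths_bp, condition,
                             transcript_ids = rownames(counts),
                             library_labels = colnames(counts),
                             assay = "rna") {
  counts <- as.matrix(counts)
  if (is.null(transcript_ids))
    transcript_ids <- paste0("tx", seq_len(nrow(counts)))
  if (is.null(library_labels))
    library_labels <- paste0("lib", seq_len(ncol(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be a non-negative integer matrix")
  if (max(counts) < .Machine$integer.max) storage.mode(counts) <- "integer"
  if (length(lengths_bp) != nrow(counts))
    stop("'lengths_bp' must have one entry per transcript")
  if (any(lengths_bp <= 0))
    stop("'lengths_bp' must be positive")
  if (length(condition) != ncol(counts))
    stop("'condition' must have one entry per library")
  condition <- as.factor(condition)
  condition <- droplevels(condition)
  if (nlevels(condition) != 2)
    stop("'condition' must have exactly 2 levels, got ", nlevels(condition))
  if (any(table(condition) < 1))
    stop("each condition needs at least one library")
  dimnames(counts) <- list(transcript_ids, library_labels)
  structure(
    list(counts = counts,
         lengths_bp = as.numeric(lengths_bp),
         condition = condition,
         transcript_ids = as.character(transcript_ids),
         library_labels = as.character(library_labels),
         assay = assay),
    class = "CountExperiment"
  )
}

#' @export
print.CountExperiment <- function(x, ...) {
  cat(sprintf("CountExperiment [%s]: %d transcripts x %d libraries\n",
              x$assay, nrow(x$counts), ncol(x$counts)))
  tb <- table(x$condition)
  cat(sprintf("conditions: %s (reference) n=%d; %s n=%d\n",
              names(tb)[1], tb[1], names(tb)[2], tb[2]))
  invisible(x)
}

#' @export
dim.CountExperiment <- function(x) dim(x$counts)
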