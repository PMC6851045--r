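# Amplicon bisulfite clone analysis: in-silico conversion of a reference,
# scoring of Sanger-sequenced clones at queried cytosines, per-position
# methylation frequencies and a text "lollipop" rendering (one row per
# clone, filled = methylated).

# Uppercase, U -> T (RNA input), validate alphabet.
normalize_sequence <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (length(s) != 1 || nchar(s) == 0) stop("empty sequence")
  s <- chartr("U", "T", s)
  bad <- which(!strsplit(s, "")[[1]] %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("invalid characters at position(s) ",
         paste(head(bad, 10), collapse = ", "))
  s
}

# 1-based positions of queried cytosines under the conversion mode.
queried_cytosines <- function(sequence, mode = c("all_c", "cpg_only")) {
  mode <- match.arg(mode)
  chars <- strsplit(normalize_sequence(sequence), "")[[1]]
  cpos <- which(chars == "C")
  if (mode == "all_c") return(cpos)
  cpos[cpos < length(chars) & chars[pmin(cpos + 1, length(chars))] == "G"]
}

#' In-silico bisulfite conversion of a reference sequence
#'
#' Applies the bisulfite chemistry to a reference: unmethylated cytosines
#' read as T. Under `all_c` (RNA bisulfite) every C becomes T; under
#' `cpg_only` (CpG-island DNA amplicons) only non-CpG cytosines are
#' converted and CpG cytosines are preserved as queried/ambiguous
#' positions. `U` on input is treated as `T`.
#'
#' @param sequence Nucleotide string over A/C/G/T/U/N.
#' @param mode `"all_c"` or `"cpg_only"`.
#' @return Converted sequence (character string).
#' @examples
#' convert_reference("ACGT", "all_c")     # "ATGT"
#' convert_reference("CCGG", "cpg_only")  # "TCGG"
#' @export
convert_reference <- function(sequence, mode = c("all_c", "cpg_only")) {
  mode <- match.arg(mode)
  s <- normalize_sequence(sequence)
  if (mode == "all_c") return(chartr("C", "T", s))
  chars <- strsplit(s, "")[[1]]
  keep <- queried_cytosines(s, "cpg_only")
  conv <- which(chars == "C")
  conv <- setdiff(conv, keep)
  chars[conv] <- "T"
  paste(chars, collapse = "")
}

#' Score bisulfite clone sequences against a reference
#'
#' Queried positions are the cytosines of the (unconverted) reference under
#' the chosen mode. At each queried position of each clone, `C` is called
#' methylated, `T` unmethylated, anything else ambiguous. Per-position
#' frequency = methylated / (methylated + unmethylated), ambiguous calls
#' excluded from the denominator; a per-clone methylation proportion is
#' computed the same way across positions.
#'
#' @param clones Named character vector of clone sequences (or
#'   `Biostrings::DNAStringSet`), each the length of `reference`.
#' @param reference The unconverted amplicon reference sequence.
#' @param mode `"all_c"` or `"cpg_only"`.
#' @param min_clones Warn when fewer clones than this are supplied
#'   (default 8, the study's minimum clone count per sample).
#' @return A `CloneMatrix`: list with `clone_ids`, `positions` (1-based),
#'   `calls` (clones x positions character matrix), `per_position_frequency`,
#'   `per_clone_percent` (proportions in `[0, 1]`), `reference`, `mode`.
#' @export
clone_analysis <- function(clones, reference, mode = c("all_c", "cpg_only"),
                           min_clones = 8) {
  mode <- match.arg(mode)
  if (inherits(clones, "XStringSet"))
    clones <- setNames(as.character(clones), names(clones))
  if (is.null(names(clones)))
    names(clones) <- sprintf("clone%02d", seq_along(clones))
  reference <- normalize_sequence(reference)
  qpos <- queried_cytosines(reference, mode)
  if (length(qpos) == 0) stop("reference contains no queried cytosine")
  clones <- vapply(clones, normalize_sequence, character(1))
  badlen <- nchar(clones) != nchar(reference)
  if (any(badlen))
    stop("clone length differs from reference: ",
         paste(names(clones)[badlen], collapse = ", "))
  if (length(clones) < min_clones)
    warning("only ", length(clones), " clones supplied (minimum advised: ",
            min_clones, ")")
  calls <- vapply(clones, function(s) {
    ch <- strsplit(s, "")[[1]][qpos]
    ifelse(ch == "C", "methylated",
           ifelse(ch == "T", "unmethylated", "ambiguous"))
  }, character(length(qpos)))
  calls <- t(matrix(calls, nrow = length(qpos)))  # clones x positions
  dimnames(calls) <- list(names(clones), paste0("C", qpos))
  freq_of <- function(x) {
    n_m <- sum(x == "methylated"); n_u <- sum(x == "unmethylated")
    if (n_m + n_u == 0) NA_real_ else n_m / (n_m + n_u)
  }
  structure(list(
    clone_ids = names(clones),
    positions = qpos,
    calls = calls,
    per_position_frequency = apply(calls, 2, freq_of),
    per_clone_percent = apply(calls, 1, freq_of),
    reference = reference,
    mode = mode
  ), class = "CloneMatrix")
}

#' Text lollipop rendering of a clone matrix
#'
#' One row per clone: filled circles for methylated, open circles for
#' unmethylated, `?` for ambiguous calls, with the clone's percent
#' methylation appended, followed by per-position frequencies.
#'
#' @param x A `CloneMatrix` from [clone_analysis()].
#' @return Character vector of lines (invisibly printed by the print
#'   method).
#' @export
render_lollipop <- function(x) {
  stopifnot(inherits(x, "CloneMatrix"))
  sym <- c(methylated = "●", unmethylated = "○", ambiguous = "?")
  w <- max(nchar(x$clone_ids))
  lines <- vapply(seq_along(x$clone_ids), function(i) {
    row <- paste(sym[x$calls[i, ]], collapse = " ")
    pct <- x$per_clone_percent[i]
    sprintf("%-*s  %s  %5s", w, x$clone_ids[i], row,
            if (is.na(pct)) "NA" else sprintf("%.0f%%", 100 * pct))
  }, character(1))
  freqs <- sprintf("%-*s  %s", w, "freq",
                   paste(sprintf("%.2f", x$per_position_frequency),
                         collapse = " "))
  pos <- sprintf("%-*s  %s", w, "site",
                 paste(x$positions, collapse = " "))
  c(pos, lines, freqs)
}

#' @export
print.CloneMatrix <- function(x, ...) {
  cat(sprintf("CloneMatrix: %d clones x %d queried cytosines (mode %s)\n",
              length(x$clone_ids), length(x$positions), x$mode))
  cat(render_lollipop(x), sep = "\n")
  invisible(x)
}
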