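# Hypergeometric gene-set over-representation against GMT collections.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per tab-separated line — set name, description,
#' then member identifiers. Duplicate members within a line are stored
#' once.
#'
#' @param path Path to a GMT file.
#' @param case `"asis"` (default) or `"upper"` to case-normalize
#'   identifiers.
#' @return Named list of character vectors (class `GeneSetCollection`).
#' @export
read_gmt <- function(path, case = c("asis", "upper")) {
  case <- match.arg(case)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed GMT line(s) with fewer than 3 fields: line ",
         paste(which(nf < 3), collapse = ", "))
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    if (case == "upper") members <- toupper(members)
    members
  })
  names(sets) <- vapply(fields, `[`, character(1), 1)
  structure(sets, class = "GeneSetCollection")
}

#' Hypergeometric over-representation of a query gene set
#'
#' For each collection set, with `N` = universe size, `K` = set size after
#' restriction to the universe, `n` = query size, `k` = overlap, computes
#' the upper-tail hypergeometric probability `P(X >= k)` of drawing at
#' least `k` set members in `n` draws without replacement, with BH FDR
#' across the retained sets. Query members outside the universe are dropped
#' with a warning; sets falling outside `[min_size, max_size]` after
#' restriction are dropped.
#'
#' @param query Character vector of identifiers (e.g. the enhanced-TE set).
#' @param collection Named list of sets ([read_gmt()]).
#' @param universe Character vector: all identifiers that could have been
#'   selected (e.g. all tested transcripts).
#' @param min_size,max_size Set-size bounds after restriction (defaults 5
#'   and 2000).
#' @return data.frame sorted by p-value with columns `set_name`, `k`, `K`,
#'   `n`, `N`, `fold_enrichment`, `p_value`, `fdr`.
#' @examples
#' u <- paste0("g", 1:10)
#' hypergeometric_enrichment(u[1:5], list(S = u[1:5]), u, min_size = 1)
#' # p = 1 / choose(10, 5) = 1/252
#' @export
hypergeometric_enrichment <- function(query, collection, universe,
                                      min_size = 5, max_size = 2000) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query identifier(s) not in universe; dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0) stop("empty query after restriction to universe")
  N <- length(universe); n <- length(query)
  restricted <- lapply(collection, function(m) intersect(unique(m), universe))
  sizes <- lengths(restricted)
  empty <- sizes == 0
  if (any(empty))
    warning(sum(empty), " set(s) empty after restriction to universe; dropped")
  keep <- sizes >= max(min_size, 1) & sizes <= max_size
  restricted <- restricted[keep]
  if (length(restricted) == 0)
    return(data.frame(set_name = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      fdr = numeric(0)))
  K <- lengths(restricted)
  k <- vapply(restricted, function(m) length(intersect(query, m)), integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(
    set_name = names(restricted),
    k = as.integer(k), K = as.integer(K),
    n = as.integer(n), N = as.integer(N),
    fold_enrichment = (k / n) / (K / N),
    p_value = p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$fdr <- bh_fdr(res$p_value)
  res[order(res$p_value, res$set_name), , drop = FALSE]
}
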