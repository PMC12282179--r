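#' Extract Cas gene annotations
#'
#' Filters a gene annotation table (e.g. from [read_gene_annotations()]) to
#' features whose name matches a Cas-gene pattern.
#'
#' @param genes tibble with `contig_id`, `start`, `end`, `strand`, `name`.
#' @param pattern regular expression on the gene name (case-insensitive).
#' @return the matching rows.
#' @export
cas_genes <- function(genes, pattern = "^cas[0-9]") {
  filter(genes, grepl(pattern, .data$name, ignore.case = TRUE))
}

#' Nearest feature by interval gap
#'
#' Gap convention follows bedtools closest: the number of bases strictly
#' between the two intervals, 0 for any overlap or abutment. Ties are broken
#' by leftmost feature start.
#'
#' @param start,end query interval, 0-based half-open.
#' @param features tibble with `start`, `end` (same contig, same convention).
#' @return a list with `feature` (one-row tibble, or `NULL` when `features`
#'   is empty) and `gap` (bp; `NA` when empty).
#' @export
nearest_feature <- function(start, end, features) {
  if (nrow(features) == 0) return(list(feature = NULL, gap = NA_integer_))
  gaps <- interval_gap(start, end, features$start, features$end)
  i <- order(gaps, features$start)[1]
  list(feature = features[i, ], gap = as.integer(gaps[i]))
}

#' Label arrays canonical or orphan by Cas-gene proximity
#'
#' An array is canonical when the minimum gap between its interval and any
#' Cas gene on the same contig is at most `max_dist` (500 bp by default);
#' it is an orphan when the gap is larger or no Cas gene shares the contig.
#'
#' @param arrays array tibble (see [detect_arrays()]).
#' @param genes gene annotation tibble; filtered with [cas_genes()] unless
#'   `already_cas = TRUE`.
#' @param max_dist distance threshold in bp.
#' @param pattern Cas-gene name pattern, passed to [cas_genes()].
#' @param already_cas set when `genes` already contains only Cas genes.
#' @return `arrays` with added columns `context` (`"canonical"`/`"orphan"`)
#'   and `cas_gap` (bp to the nearest Cas gene; `NA` when none on contig).
#' @export
classify_context <- function(arrays, genes, max_dist = 500L,
                             pattern = "^cas[0-9]", already_cas = FALSE) {
  cg <- if (already_cas) genes else cas_genes(genes, pattern)
  gap <- vapply(seq_len(nrow(arrays)), function(i) {
    same <- filter(cg, .data$contig_id == arrays$contig_id[i])
    nearest_feature(arrays$start[i], arrays$end[i], same)$gap
  }, integer(1))
  arrays |>
    mutate(cas_gap = gap,
           context = ifelse(!is.na(gap) & gap <= max_dist,
                            "canonical", "orphan"))
}
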