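#' Reference direct-repeat catalog
#'
#' A small built-in catalog of representative direct repeats for the two
#' system types this package targets: palindromic type I-E repeats (29 bp,
#' 7 bp stem, 4 nt tetraloop) and short type II-C repeats. Queries are typed
#' by nearest catalog entry under strand-aware Levenshtein distance; users
#' can supply their own catalog for other clades.
#'
#' @return a tibble with columns `repeat_seq`, `type`, `subtype`.
#' @examples
#' default_repeat_catalog()
#' @export
default_repeat_catalog <- function() {
  tibble(
    repeat_seq = c(
      # tail5(4) + arm(7) + tetraloop(4) + revcomp(arm)(7) + tail3(7)
      "GTTCGCCGAGCTTCAGCTCGGCAGAACCG",
      "GTTCGCCGAGCTTCGGCTCGGCAGAACCG",
      # non-palindromic II-C repeats
      "ATTTCAATCCACGCACTCATGTAGAGTGCGACCGAT",
      "GTTGTAGCTCCCTTTCTCATTTCGCAGTGCTACAAT"
    ),
    type = c("I", "I", "II", "II"),
    subtype = c("I-E", "I-E", "II-C", "II-C")
  )
}

#' @rdname default_repeat_catalog
#' @param path TSV with columns `repeat_seq`, `type`, `subtype`.
#' @export
read_repeat_catalog <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  validate_catalog(as_tibble(x))
}

validate_catalog <- function(catalog) {
  req <- c("repeat_seq", "type", "subtype")
  if (!all(req %in% names(catalog)) || nrow(catalog) == 0) {
    abort("repeat catalog must be non-empty with columns repeat_seq, type, subtype")
  }
  if (anyDuplicated(catalog$repeat_seq)) abort("catalog repeat sequences must be unique")
  assert_dna(catalog$repeat_seq, allow_n = FALSE, arg = "catalog repeat_seq")
  catalog
}

#' Type direct repeats by edit distance to a catalog
#'
#' Each query is compared to every catalog entry on both strands; the entry
#' minimizing Levenshtein distance wins (ties by distance, then catalog
#' order). A repeat is accepted as a true CRISPR repeat when its distance is
#' at most `max_edits` (default 4).
#'
#' @param queries character vector of repeat sequences (>= 16 bp).
#' @param catalog a repeat catalog tibble (see [default_repeat_catalog()]).
#' @param max_edits maximum accepted edit distance.
#' @return a tibble with one row per query: `query`, `best_repeat`, `type`,
#'   `subtype`, `edit_distance`, `accepted`.
#' @examples
#' classify_repeats(default_repeat_catalog()$repeat_seq[1])
#' @export
classify_repeats <- function(queries, catalog = default_repeat_catalog(),
                             max_edits = 4L) {
  validate_catalog(catalog)
  if (length(queries) == 0) {
    return(tibble(query = character(), best_repeat = character(),
                  type = character(), subtype = character(),
                  edit_distance = integer(), accepted = logical()))
  }
  if (any(nchar(queries) < 16)) abort("repeat queries must be >= 16 bp")
  assert_dna(queries, allow_n = FALSE, arg = "query")
  d_fwd <- utils::adist(queries, catalog$repeat_seq)
  d_rev <- utils::adist(revcomp(queries), catalog$repeat_seq)
  d <- pmin(d_fwd, d_rev)
  best <- apply(d, 1, which.min)  # which.min takes the first (catalog order)
  dist <- d[cbind(seq_along(queries), best)]
  tibble(
    query = queries,
    best_repeat = catalog$repeat_seq[best],
    type = catalog$type[best],
    subtype = catalog$subtype[best],
    edit_distance = as.integer(dist),
    accepted = dist <= max_edits
  )
}

#' @rdname classify_repeats
#' @param query a single repeat sequence.
#' @export
classify_repeat <- function(query, catalog = default_repeat_catalog(),
                            max_edits = 4L) {
  classify_repeats(query, catalog, max_edits)
}

#' Fold a direct repeat into its maximal hairpin
#'
#' Searches every pair of exact reverse-complement arms (no wobble pairs, no
#' bulges) with the 5' arm entirely left of the 3' arm, and returns the pair
#' maximizing stem length; ties are broken by smallest loop, then leftmost
#' 5' arm. Loops shorter than `min_loop` (default 3 nt, the physical minimum
#' for a hairpin turn) are not considered.
#'
#' @param repeat_seq repeat sequence over ACGT.
#' @param min_stem minimum stem length in bp to report a hairpin.
#' @param min_loop minimum loop length in nt.
#' @return a one-row tibble with `stem_len`, `arm5_start`, `arm3_end`
#'   (0-based half-open offsets within the repeat), `loop_seq`, `tail5`,
#'   `tail3`; or `NULL` when no stem reaches `min_stem`.
#' @examples
#' fold_hairpin("TATTGCCGAGCTTCAGCTCGGCAGAAC")
#' @export
fold_hairpin <- function(repeat_seq, min_stem = 5L, min_loop = 3L) {
  assert_dna(repeat_seq, allow_n = FALSE, arg = "repeat")
  b <- strsplit(repeat_seq, "")[[1]]
  n <- length(b)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- NULL
  for (p0 in seq_len(n)) {
    for (q0 in seq_len(n)) {
      if (q0 - p0 - 1 < min_loop) next
      # grow the stem outward-in from pair (p0, q0)
      L <- 0L
      while (p0 + L <= n && q0 - L >= 1 &&
             (q0 - L) - (p0 + L) - 1 >= min_loop &&
             comp[[b[p0 + L]]] == b[q0 - L]) {
        L <- L + 1L
      }
      if (L < min_stem) next
      loop_len <- (q0 - L + 1) - (p0 + L - 1) - 1
      cand <- c(L, loop_len, p0)
      if (is.null(best) ||
          L > best[1] ||
          (L == best[1] && loop_len < best[2]) ||
          (L == best[1] && loop_len == best[2] && p0 < best[3])) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  L <- best[1]; p0 <- best[3]
  q_end <- p0 + L - 1 + best[2] + L  # 1-based position of arm3 last base
  tibble(
    stem_len = as.integer(L),
    arm5_start = p0 - 1L,
    arm3_end = as.integer(q_end),
    loop_seq = substr(repeat_seq, p0 + L, p0 + L + best[2] - 1),
    tail5 = substr(repeat_seq, 1, p0 - 1),
    tail3 = if (q_end < n) substr(repeat_seq, q_end + 1, n) else ""
  )
}

#' Tetraloop census across type I-E arrays
#'
#' Folds the consensus repeat of each type I-E array and tabulates hairpin
#' loop sequences by strain and canonical/orphan context. Arrays whose repeat
#' does not fold are tallied under loop `"NA"`.
#'
#' @param arrays array tibble with columns `strain_id`, `context`,
#'   `consensus_repeat` and `subtype` (only `I-E` rows are used).
#' @param min_stem,min_loop passed to [fold_hairpin()].
#' @return a tibble `strain_id`, `context`, `tetraloop`, `n`.
#' @export
tetraloop_census <- function(arrays, min_stem = 5L, min_loop = 3L) {
  empty <- tibble(strain_id = character(), context = character(),
                  tetraloop = character(), n = integer())
  if (nrow(arrays) == 0) return(empty)
  ie <- filter(arrays, .data$subtype == "I-E")
  if (nrow(ie) == 0) return(empty)
  loops <- vapply(ie$consensus_repeat, function(r) {
    hp <- fold_hairpin(r, min_stem = min_stem, min_loop = min_loop)
    if (is.null(hp)) "NA" else hp$loop_seq
  }, character(1), USE.NAMES = FALSE)
  ie |>
    mutate(tetraloop = loops) |>
    count(.data$strain_id, .data$context, .data$tetraloop, name = "n") |>
    arrange(.data$strain_id, .data$context, .data$tetraloop)
}
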