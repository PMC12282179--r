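#' Collapse duplicate spacers within a genome
#'
#' Exact duplicates and reverse-complement duplicates collapse to one
#' representative on the canonical strand (lexicographic minimum of the
#' sequence and its reverse complement), so internal array redundancy does
#' not inflate cross-genome match counts.
#'
#' @param spacers tibble with columns `strain_id` and `seq` (other columns
#'   are kept from the first occurrence).
#' @return the deduplicated tibble with `seq` on the canonical strand.
#' @export
dedupe_spacers <- function(spacers) {
  spacers |>
    mutate(seq = canonical_strand(.data$seq)) |>
    distinct(.data$strain_id, .data$seq, .keep_all = TRUE)
}

## integer encoding for vectorized comparison
seq_to_int <- function(x) utf8ToInt(x)

## identity profile of `spacer` against every offset of `ref` (both strings),
## ungapped, denominator = spacer length; returns numeric vector over offsets
scan_identity <- function(spacer_int, ref_int) {
  L <- length(spacer_int); n <- length(ref_int)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  counts <- integer(nw)
  for (j in seq_len(L)) {
    counts <- counts + (ref_int[j:(j + nw - 1L)] == spacer_int[j])
  }
  counts / L
}

#' Match spacers against reference sequences
#'
#' Exhaustive all-offsets, both-strands scan: for each spacer, every
#' placement with identity at least `min_identity` is reported. Identity is
#' the number of matching positions divided by the spacer length, ungapped
#' by default; `mode = "gapped"` instead aligns the spacer end-to-end
#' against local windows of length `L +/- max_gaps` at each offset (identity
#' `(L - edits)/L`), which is exhaustive but markedly slower and intended
#' for short references. Placements overlapping the spacer's own source
#' array interval (columns `self_contig`, `self_start`, `self_end`, when
#' present) are removed as self-hits.
#'
#' @param spacers tibble with `query_id` and `seq` (optionally the self-hit
#'   columns above), or a character vector.
#' @param reference named character vector of reference sequences.
#' @param min_identity retention threshold in (0.5, 1].
#' @param mode `"ungapped"` or `"gapped"`.
#' @param max_gaps gap budget for `mode = "gapped"`.
#' @return a tibble `query_id`, `target_id`, `start`, `end` (0-based
#'   half-open forward-strand coordinates), `strand`, `identity` (percent).
#' @export
match_spacers_to_reference <- function(spacers, reference, min_identity = 0.80,
                                       mode = c("ungapped", "gapped"),
                                       max_gaps = 2L) {
  mode <- match.arg(mode)
  if (min_identity <= 0.5 || min_identity > 1) {
    abort("min_identity must be in (0.5, 1]")
  }
  if (is.character(spacers)) {
    spacers <- tibble(query_id = names(spacers) %||%
                        sprintf("spacer%d", seq_along(spacers)),
                      seq = unname(spacers))
  }
  if (any(nchar(spacers$seq) < 16)) abort("spacers must be >= 16 bp")
  if (is.null(names(reference))) {
    names(reference) <- sprintf("ref%d", seq_along(reference))
  }
  ref_int <- lapply(reference, seq_to_int)
  out <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$seq[i]
    L <- nchar(sp)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") sp else revcomp(sp)
      qi <- seq_to_int(q)
      for (tid in names(reference)) {
        idf <- if (mode == "ungapped") {
          scan_identity(qi, ref_int[[tid]])
        } else {
          gapped_identity_profile(q, reference[[tid]], max_gaps)
        }
        hit <- which(idf >= min_identity)
        if (length(hit)) {
          out[[length(out) + 1L]] <- tibble(
            query_id = spacers$query_id[i], target_id = tid,
            start = hit - 1L, end = hit - 1L + L, strand = strand,
            identity = 100 * idf[hit]
          )
        }
      }
    }
  }
  m <- if (length(out)) bind_rows(out) else {
    tibble(query_id = character(), target_id = character(),
           start = integer(), end = integer(), strand = character(),
           identity = numeric())
  }
  # self-hit removal: placements overlapping the query's own array interval
  if (all(c("self_contig", "self_start", "self_end") %in% names(spacers)) &&
      nrow(m)) {
    m <- left_join(m,
                   select(spacers, "query_id", "self_contig", "self_start",
                          "self_end"),
                   by = "query_id")
    self <- !is.na(m$self_contig) & m$target_id == m$self_contig &
      interval_gap(m$start, m$end, m$self_start, m$self_end) == 0 &
      m$start < m$self_end & m$end > m$self_start
    m <- m[!self, !names(m) %in% c("self_contig", "self_start", "self_end")]
  }
  arrange(m, .data$query_id, .data$target_id, .data$start, .data$strand)
}

## best end-to-end gapped identity of q at each offset of ref:
## align q against windows ref[i, i + L + d) for d in -max_gaps..max_gaps,
## identity = (L - min edit distance) / L, attributed to offset i
gapped_identity_profile <- function(q, ref, max_gaps = 2L) {
  L <- nchar(q); n <- nchar(ref)
  if (n < L - max_gaps) return(numeric(0))
  nw <- n - L + 1L
  if (nw < 1L) return(numeric(0))
  best <- numeric(nw)
  for (d in -max_gaps:max_gaps) {
    wlen <- L + d
    if (wlen < 1) next
    starts <- seq_len(min(nw, n - wlen + 1L))
    if (!length(starts)) next
    wins <- substring(ref, starts, starts + wlen - 1L)
    dist <- as.integer(utils::adist(q, wins))
    idf <- (L - dist) / L
    best[starts] <- pmax(best[starts], idf)
  }
  best
}

#' Pairwise spacer sharing between strains
#'
#' For every ordered strain pair, counts the query strain's unique spacers
#' that have at least one placement at `min_identity` or better among the
#' partner strain's unique spacers (both strands, ungapped sliding identity
#' with the query length as denominator). `min_identity = 1` reproduces
#' exact (or reverse-complement) sharing.
#'
#' @param spacers tibble with `strain_id`, `seq`; deduplicated internally
#'   with [dedupe_spacers()].
#' @param min_identity threshold in (0.5, 1].
#' @return an object of class `sharing_summary`: a list with `counts`
#'   (tibble `query_strain`, `target_strain`, `n_shared`), `totals`
#'   (tibble `strain_id`, `n_spacers`) and `min_identity`.
#' @export
sharing_matrix <- function(spacers, min_identity = 0.80) {
  uniq <- dedupe_spacers(spacers)
  strains <- sort(unique(uniq$strain_id))
  if (length(strains) < 2) abort("sharing_matrix needs >= 2 strains")
  by_strain <- split(uniq$seq, uniq$strain_id)
  hits <- function(qs, ts) {
    # does query spacer qs match any target spacer at >= min_identity?
    ti <- lapply(ts, seq_to_int)
    vapply(qs, function(q) {
      for (qq in unique(c(q, revcomp(q)))) {
        qi <- seq_to_int(qq)
        for (t in ti) {
          if (length(t) >= length(qi) &&
              any(scan_identity(qi, t) >= min_identity)) return(TRUE)
        }
      }
      FALSE
    }, logical(1), USE.NAMES = FALSE)
  }
  grid <- expand.grid(query_strain = strains, target_strain = strains,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$query_strain != grid$target_strain, ]
  counts <- bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    a <- grid$query_strain[i]; b <- grid$target_strain[i]
    tibble(query_strain = a, target_strain = b,
           n_shared = sum(hits(by_strain[[a]], by_strain[[b]])))
  }))
  structure(list(
    counts = arrange(counts, .data$query_strain, .data$target_strain),
    totals = uniq |> count(.data$strain_id, name = "n_spacers"),
    min_identity = min_identity
  ), class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("<sharing_summary> %d strains at >= %.0f%% identity\n",
              nrow(x$totals), 100 * x$min_identity))
  print(tidyr::pivot_wider(x$counts, names_from = "target_strain",
                           values_from = "n_shared"))
  invisible(x)
}

#' @rdname sharing_matrix
#' @param x a `sharing_summary`.
#' @param path output TSV.
#' @export
write_sharing_tsv <- function(x, path) {
  readr::write_tsv(x$counts, path)
  invisible(path)
}
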