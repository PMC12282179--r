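#' Detection parameters for repeat-spacer array finding
#'
#' Defaults follow the published behavior of CRT-like first-pass detectors:
#' exact 23-mer seeds, repeats 19-38 bp, spacers 19-48 bp, at least 3 repeat
#' copies. `boundary_agree` is the fraction of repeat copies that must agree
#' at a column for the repeat boundary to extend over it; the default (1.0,
#' unanimity among copies covering the column) keeps boundaries exact on
#' clean assemblies, and can be relaxed (e.g. 0.75) for degraded repeats.
#' `max_spacer_identity` is the tandem-repeat guard: arrays whose spacers are
#' near-copies of each other are rejected. `max_repeat_edits` rejects arrays
#' with a repeat copy too far from the consensus.
#'
#' @param seed_k exact seed k-mer length.
#' @param min_repeat_len,max_repeat_len repeat length bounds (bp).
#' @param min_spacer_len,max_spacer_len spacer length bounds (bp).
#' @param min_repeats minimum repeat copies (>= 2).
#' @param max_repeat_edits maximum edit distance of any copy from consensus.
#' @param boundary_agree column agreement fraction for boundary extension.
#' @param max_spacer_identity tandem-repeat guard threshold (mean pairwise
#'   spacer identity).
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(seed_k = 23L, min_repeat_len = 19L,
                             max_repeat_len = 38L, min_spacer_len = 19L,
                             max_spacer_len = 48L, min_repeats = 3L,
                             max_repeat_edits = 3L, boundary_agree = 1.0,
                             max_spacer_identity = 0.6) {
  stopifnot(min_repeat_len <= max_repeat_len,
            min_spacer_len <= max_spacer_len,
            min_repeats >= 2, seed_k <= max_repeat_len)
  structure(as.list(environment()), class = "detection_params")
}

empty_arrays <- function() {
  tibble(strain_id = character(), contig_id = character(),
         array_idx = integer(), start = integer(), end = integer(),
         n_repeats = integer(), n_spacers = integer(),
         consensus_repeat = character(),
         repeats = list(), spacers = list())
}

#' Detect CRISPR arrays in a contig
#'
#' Finds runs of near-identical direct repeats separated by spacers. Exact
#' `seed_k`-mer recurrences at spacer-compatible distances seed candidates;
#' seed occurrences are extended to full repeat boundaries column-by-column
#' while at least `boundary_agree` of the copies agree; candidate arrays are
#' then extended outward by whole repeat units while a flanking window stays
#' within `max_repeat_edits` of the consensus, and finally filtered by the
#' tandem-repeat and repeat-degeneracy guards. Candidates spanning `N` are
#' dropped.
#'
#' @param contig a DNA string over ACGTN.
#' @param params a [detection_params()] object.
#' @param strain_id,contig_id identifiers attached to the output.
#' @return a tibble of arrays sorted by `start` with columns `strain_id`,
#'   `contig_id`, `array_idx`, `start`, `end` (0-based half-open),
#'   `n_repeats`, `n_spacers`, `consensus_repeat`, and list-columns
#'   `repeats`, `spacers` holding the ordered unit sequences. Repeats and
#'   spacers concatenate, in order, to the contig substring `[start, end)`.
#' @export
detect_arrays <- function(contig, params = detection_params(),
                          strain_id = NA_character_,
                          contig_id = NA_character_) {
  assert_dna(contig, allow_n = TRUE, arg = "contig")
  k <- params$seed_k
  n <- nchar(contig)
  if (n < 2L * k + params$min_spacer_len) return(empty_arrays())

  km <- kmers(contig, k)
  pos <- 0:(n - k)
  keep <- !grepl("N", km, fixed = TRUE)
  km <- km[keep]; pos <- pos[keep]
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  km <- km[dup]; pos <- pos[dup]
  if (!length(km)) return(empty_arrays())

  d_lo <- params$min_repeat_len + params$min_spacer_len
  d_hi <- params$max_repeat_len + params$max_spacer_len

  cands <- list()
  for (p in unname(split(pos, factor(km, levels = unique(km))))) {
    if (length(p) < params$min_repeats) next
    # maximal runs of occurrences with spacer-compatible consecutive spacing
    ok <- diff(p) >= d_lo & diff(p) <= d_hi
    run_id <- cumsum(c(TRUE, !ok))
    for (run in split(p, run_id)) {
      if (length(run) >= params$min_repeats) {
        cands[[length(cands) + 1L]] <- run
      }
    }
  }
  if (!length(cands)) return(empty_arrays())

  arrays <- list()
  for (run in cands) {
    a <- extend_candidate(contig, run, k, params)
    if (!is.null(a)) arrays[[length(arrays) + 1L]] <- a
  }
  if (!length(arrays)) return(empty_arrays())

  # dedupe candidates that converged to the same or overlapping array: keep,
  # per overlap group, the one with most repeats, then best copy agreement
  # (fewest total edits to consensus), then leftmost
  starts <- vapply(arrays, function(a) a$start, integer(1))
  ends <- vapply(arrays, function(a) a$end, integer(1))
  nreps <- vapply(arrays, function(a) length(a$repeats), integer(1))
  edits <- vapply(arrays, function(a) a$edits, numeric(1))
  ord <- order(starts, -nreps, edits)
  arrays <- arrays[ord]; starts <- starts[ord]; ends <- ends[ord]
  nreps <- nreps[ord]; edits <- edits[ord]
  grp <- integer(length(arrays)); g <- 0L; gend <- -1L
  for (i in seq_along(arrays)) {
    if (starts[i] >= gend) g <- g + 1L
    grp[i] <- g
    gend <- max(gend, ends[i])
  }
  pick <- vapply(split(seq_along(arrays), grp), function(idx) {
    idx[order(-nreps[idx], edits[idx], starts[idx])][1]
  }, integer(1))
  arrays <- arrays[sort(pick)]

  rows <- lapply(arrays, function(a) {
    tibble(strain_id = strain_id, contig_id = contig_id, array_idx = NA_integer_,
           start = a$start, end = a$end,
           n_repeats = length(a$repeats), n_spacers = length(a$spacers),
           consensus_repeat = a$consensus,
           repeats = list(a$repeats), spacers = list(a$spacers))
  })
  out <- bind_rows(rows) |> arrange(.data$start)
  out$array_idx <- seq_len(nrow(out))
  out
}

## extend one seed run to a full array; NULL when filtered out
extend_candidate <- function(contig, run, k, params) {
  n <- nchar(contig)
  m <- length(run)
  col_base <- function(p) substring(contig, p + 1, p + 1)

  agree <- function(off) {
    p <- run + off
    if (any(p < 0 | p >= n)) return(FALSE)
    b <- col_base(p)
    if (any(b == "N")) return(FALSE)
    max(table(b)) / m >= params$boundary_agree
  }
  # grow left from seed starts and right from seed ends,
  # capped by the repeat length bound and by not eating the next seed copy
  L <- 0L
  while (k + L < params$max_repeat_len &&
         (m < 2 || min(diff(run)) - L - k > 0) && agree(-L - 1L)) L <- L + 1L
  R <- 0L
  while (k + L + R < params$max_repeat_len &&
         (m < 2 || min(diff(run)) - L - k - R > 0) && agree(k + R)) R <- R + 1L

  rep_start <- run - L
  rep_len <- k + L + R
  if (rep_len < params$min_repeat_len) return(NULL)
  reps <- sub0(contig, rep_start, rep_start + rep_len)
  cons <- consensus_repeat(reps)

  # maximality: pull in flanking repeat units within edit budget
  probe <- function(at) {
    # best additional unit start for a repeat preceding/following the array
    best <- NULL
    for (gap in params$min_spacer_len:params$max_spacer_len) {
      s <- at(gap)
      if (s < 0 || s + rep_len > n) next
      cand <- sub0(contig, s, s + rep_len)
      if (grepl("N", cand, fixed = TRUE)) next
      d <- edit_distance(cand, cons)
      if (d <= params$max_repeat_edits && (is.null(best) || d < best$d)) {
        best <- list(s = s, d = d)
      }
    }
    best
  }
  repeat {
    b <- probe(function(gap) rep_start[1] - gap - rep_len)
    if (is.null(b)) break
    rep_start <- c(b$s, rep_start)
  }
  repeat {
    last <- rep_start[length(rep_start)]
    b <- probe(function(gap) last + rep_len + gap)
    if (is.null(b)) break
    rep_start <- c(rep_start, b$s)
  }
  # refine boundaries over the final copy set: a terminal column is kept
  # only if it meets the same agreement rule that justifies extension
  # (guards against seeds that straddle the repeat/spacer junction)
  col_ok <- function(off) {
    b <- substring(contig, rep_start + off + 1, rep_start + off + 1)
    max(table(b)) / length(rep_start) >= params$boundary_agree
  }
  while (rep_len > params$min_repeat_len && !col_ok(0L)) {
    rep_start <- rep_start + 1L
    rep_len <- rep_len - 1L
  }
  while (rep_len > params$min_repeat_len && !col_ok(rep_len - 1L)) {
    rep_len <- rep_len - 1L
  }
  reps <- sub0(contig, rep_start, rep_start + rep_len)
  cons <- consensus_repeat(reps)

  # spacers between consecutive repeat copies
  sp_start <- rep_start[-length(rep_start)] + rep_len
  sp_end <- rep_start[-1]
  sp_len <- sp_end - sp_start
  if (any(sp_len < params$min_spacer_len | sp_len > params$max_spacer_len)) {
    return(NULL)
  }
  spacers <- sub0(contig, sp_start, sp_end)

  # repeat-degeneracy guard
  if (any(utils::adist(reps, cons) > params$max_repeat_edits)) return(NULL)
  # tandem-repeat guard: mean pairwise spacer identity
  if (length(spacers) >= 2) {
    d <- utils::adist(spacers)
    len <- outer(nchar(spacers), nchar(spacers), pmax)
    ident <- 1 - d / len
    if (mean(ident[upper.tri(ident)]) > params$max_spacer_identity) return(NULL)
  }
  list(start = rep_start[1], end = rep_start[length(rep_start)] + rep_len,
       repeats = unname(reps), spacers = unname(spacers), consensus = cons,
       edits = sum(utils::adist(reps, cons)))
}

#' Per-column majority consensus of repeat copies
#'
#' @param repeats non-empty character vector of (near) equal-length repeat
#'   copies. Columns beyond a shorter copy's length are tallied over the
#'   copies that cover them.
#' @return the consensus string; ties broken by lexicographic order of base.
#' @examples
#' consensus_repeat(c("ACGT", "ACGA", "ACGT"))
#' @export
consensus_repeat <- function(repeats) {
  if (length(repeats) == 0) abort("consensus of an empty repeat list")
  len <- max(nchar(repeats))
  cols <- vapply(seq_len(len), function(j) {
    b <- substring(repeats, j, j)
    b <- b[b != ""]
    tab <- table(b)
    names(tab)[which.max(tab)]  # which.max -> first max, names sorted: lexicographic tie-break
  }, character(1))
  paste(cols, collapse = "")
}

#' Scan an assembly for CRISPR arrays
#'
#' Applies [detect_arrays()] to every contig of an assembly and numbers the
#' arrays per strain.
#'
#' @param assembly a named character vector of contigs, or a FASTA path.
#' @param params a [detection_params()] object.
#' @param strain_id strain identifier attached to the output.
#' @return an array tibble (see [detect_arrays()]).
#' @export
strain_scan <- function(assembly, params = detection_params(),
                        strain_id = NA_character_) {
  if (is.character(assembly) && length(assembly) == 1 && file.exists(assembly) &&
      is.null(names(assembly))) {
    assembly <- read_assembly(assembly)
  }
  if (anyDuplicated(names(assembly))) abort("duplicate contig ids")
  out <- bind_rows(lapply(names(assembly), function(cid) {
    detect_arrays(assembly[[cid]], params, strain_id = strain_id,
                  contig_id = cid)
  }))
  if (nrow(out) == 0) return(empty_arrays())
  out$array_idx <- seq_len(nrow(out))
  out
}

#' Write a detected-array table
#'
#' Flat TSV of the per-array summary columns (list-columns dropped), the bulk
#' collection companion to [write_array_fasta()].
#'
#' @param arrays array tibble.
#' @param path output TSV.
#' @export
write_array_tsv <- function(arrays, path) {
  readr::write_tsv(select(arrays, -"repeats", -"spacers"), path)
  invisible(path)
}
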