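#' Parameters for read-based spacer recovery
#'
#' Defaults mirror the published defaults of read-space CRISPR detectors:
#' a 23-mer must recur at least 26 bp away within one read to seed a repeat;
#' a group must gather at least 2 repeat instances and 2 distinct spacers;
#' partial spacers shorter than 16 bp are discarded.
#'
#' @param k seed k-mer length.
#' @param min_sep minimum separation between k-mer recurrences in a read.
#' @param min_repeats minimum repeat instances for a group.
#' @param min_spacers minimum distinct spacers for a group.
#' @param min_partial minimum spacer length in bp.
#' @param max_spacer_len maximum spacer (or partial-spacer) length in bp;
#'   longer inter-repeat or flanking stretches are treated as non-spacer
#'   sequence and dropped.
#' @param boundary_agree column agreement fraction for repeat boundary
#'   refinement across the reads of a group.
#' @param max_repeat_len repeat length cap in bp.
#' @return a list of class `read_spacer_params`.
#' @export
read_spacer_params <- function(k = 23L, min_sep = 26L, min_repeats = 2L,
                               min_spacers = 2L, min_partial = 16L,
                               max_spacer_len = 48L,
                               boundary_agree = 0.75, max_repeat_len = 40L) {
  structure(as.list(environment()), class = "read_spacer_params")
}

#' Remove read pairs mapping to the host
#'
#' A pair is retained only when NEITHER mate maps to the host (the
#' keep-both-unmapped semantics of samtools flag filtering). Mapping is a
#' desk-scale surrogate for a read aligner: a mate maps when it shares at
#' least one exact `k`-mer (default 31) with either strand of the host
#' genome.
#'
#' @param reads tibble with `seq1`, `seq2` (one row per pair).
#' @param host host genome as a DNA string (or vector of contigs).
#' @param k k-mer size for the mapping surrogate.
#' @return the retained rows of `reads`.
#' @export
host_filter <- function(reads, host, k = 31L) {
  if (!all(c("seq1", "seq2") %in% names(reads))) {
    abort("host_filter needs paired reads with seq1/seq2 columns")
  }
  hk <- unique(unlist(lapply(c(host, revcomp(host)), kmers, k = k)))
  maps <- function(seqs) {
    kl <- lapply(seqs, kmers, k = k)
    hit <- unlist(kl) %in% hk
    idx <- rep(seq_along(seqs), lengths(kl))
    out <- logical(length(seqs))
    if (length(idx)) out[unique(idx[hit])] <- TRUE
    out
  }
  reads[!maps(reads$seq1) & !maps(reads$seq2), ]
}

empty_groups <- function() {
  tibble(sample_id = character(), group_id = character(),
         consensus_repeat = character(), n_repeat_instances = integer(),
         n_spacers = integer(), spacers = list())
}

## locate all exact occurrences of pattern (fixed) in each string; 0-based
locate_fixed <- function(strings, pattern) {
  lapply(gregexpr(pattern, strings, fixed = TRUE), function(m) {
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  })
}

#' Recover CRISPR spacers from unassembled reads
#'
#' Per read, any `k`-mer recurring at least `min_sep` bp downstream seeds a
#' repeat candidate; candidates sharing k-mers across reads (either strand)
#' are grouped, repeat boundaries are refined by column agreement across all
#' grouped instances, and spacers are read out as the sequences between
#' consecutive repeat occurrences in each read. Sequences flanking the
#' outermost occurrence of a read are reported as partial spacers
#' (`full = FALSE`). Groups below `min_repeats` repeat instances or
#' `min_spacers` distinct spacers are discarded, as are spacers shorter than
#' `min_partial`.
#'
#' @param seqs character vector of read sequences (one read file; run mates
#'   separately and combine with [merge_groups()]).
#' @param sample_id sample label carried into the output.
#' @param params a [read_spacer_params()] object.
#' @return a group tibble: `sample_id`, `group_id`, `consensus_repeat`
#'   (lexicographically canonical strand), `n_repeat_instances`,
#'   `n_spacers`, and a `spacers` list-column of tibbles
#'   (`seq`, `full`, `sample_id`).
#' @export
extract_read_spacers <- function(seqs, sample_id = "sample",
                                 params = read_spacer_params()) {
  k <- params$k
  if (!length(seqs)) return(empty_groups())
  assert_dna(seqs, allow_n = TRUE, arg = "reads")

  # per read: canonical forms of k-mers recurring >= min_sep apart
  recurring <- lapply(seqs, function(r) {
    km <- kmers(r, k)
    if (length(km) < 2) return(character(0))
    dup <- unique(km[duplicated(km)])
    dup <- dup[!grepl("N", dup, fixed = TRUE)]
    if (!length(dup)) return(character(0))
    keep <- vapply(dup, function(x) {
      p <- which(km == x)
      (p[length(p)] - p[1]) >= params$min_sep
    }, logical(1))
    unique(canonical_strand(dup[keep]))
  })
  all_kmers <- unique(unlist(recurring))
  if (!length(all_kmers)) return(empty_groups())

  # union-find over k-mers co-occurring within a read
  parent <- seq_along(all_kmers)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (rk in recurring) {
    if (length(rk) < 2) next
    ids <- match(rk, all_kmers)
    r0 <- find(ids[1])
    for (j in ids[-1]) parent[find(j)] <- r0
  }
  comp <- vapply(seq_along(all_kmers), find, integer(1))

  groups <- list()
  for (cid in unique(comp)) {
    members <- all_kmers[comp == cid]
    # anchor: member recurring in the most reads, ties by sequence
    n_reads <- vapply(members, function(x) {
      sum(vapply(recurring, function(rk) x %in% rk, logical(1)))
    }, integer(1))
    anchor <- members[order(-n_reads, members)][1]
    g <- build_read_group(seqs, anchor, params)
    if (!is.null(g)) groups[[length(groups) + 1L]] <- g
  }
  if (!length(groups)) return(empty_groups())
  out <- bind_rows(groups)
  out$sample_id <- sample_id
  out$group_id <- sprintf("%s_g%d", sample_id, seq_len(nrow(out)))
  out$spacers <- lapply(out$spacers, function(s) mutate(s, sample_id = sample_id))
  select(out, "sample_id", "group_id", "consensus_repeat",
         "n_repeat_instances", "n_spacers", "spacers")
}

## build one group around an anchor k-mer: refine the repeat across reads,
## then read out spacers; NULL when the group fails the minimum filters
build_read_group <- function(seqs, anchor, params) {
  k <- params$k
  # all anchor instances, reads oriented so the anchor reads forward
  inst <- list()
  for (pat in unique(c(anchor, revcomp(anchor)))) {
    loc <- locate_fixed(seqs, pat)
    for (i in which(lengths(loc) > 0)) {
      r <- if (pat == anchor) seqs[i] else revcomp(seqs[i])
      p <- if (pat == anchor) loc[[i]] else nchar(seqs[i]) - (loc[[i]] + k)
      for (p0 in p) inst[[length(inst) + 1L]] <- list(read = r, pos = p0)
    }
  }
  if (length(inst) < 2) return(NULL)
  rd <- vapply(inst, `[[`, character(1), "read")
  ps <- vapply(inst, function(x) as.integer(x$pos), integer(1))

  col_agree <- function(off) {
    at <- ps + off
    ok <- at >= 0 & at < nchar(rd)
    if (sum(ok) < 2) return(NULL)
    b <- substring(rd[ok], at[ok] + 1, at[ok] + 1)
    tab <- sort(table(b), decreasing = TRUE)
    if (tab[1] / sum(tab) >= params$boundary_agree) names(tab)[1] else NULL
  }
  L <- 0L; left <- character(0)
  while (k + L < params$max_repeat_len) {
    b <- col_agree(-L - 1L); if (is.null(b)) break
    left <- c(b, left); L <- L + 1L
  }
  R <- 0L; right <- character(0)
  while (k + L + R < params$max_repeat_len) {
    b <- col_agree(k + R); if (is.null(b)) break
    right <- c(right, b); R <- R + 1L
  }
  consensus <- paste(c(left, anchor, right), collapse = "")
  canon <- canonical_strand(consensus)

  # read out spacers around exact consensus occurrences
  sp <- list(); n_inst <- 0L
  fwd <- locate_fixed(seqs, canon)
  rev_ <- if (canon != revcomp(canon)) locate_fixed(seqs, revcomp(canon)) else
    lapply(seqs, function(x) integer(0))
  rlen <- nchar(canon)
  for (i in seq_along(seqs)) {
    use_fwd <- length(fwd[[i]]) >= length(rev_[[i]])
    r <- if (use_fwd) seqs[i] else revcomp(seqs[i])
    p <- if (use_fwd) fwd[[i]] else nchar(seqs[i]) - (rev_[[i]] + rlen)
    p <- sort(p)
    if (!length(p)) next
    n_inst <- n_inst + length(p)
    n <- nchar(r)
    if (length(p) > 1) {
      s0 <- p[-length(p)] + rlen; s1 <- p[-1]
      full <- sub0(r, s0, s1)
      sp[[length(sp) + 1L]] <- tibble(seq = full, full = TRUE)
    }
    flanks <- c(if (p[1] > 0) sub0(r, 0, p[1]),
                if (p[length(p)] + rlen < n) sub0(r, p[length(p)] + rlen, n))
    if (length(flanks)) {
      sp[[length(sp) + 1L]] <- tibble(seq = flanks, full = FALSE)
    }
  }
  if (n_inst < params$min_repeats) return(NULL)
  spacers <- bind_rows(sp) |>
    filter(nchar(.data$seq) >= params$min_partial,
           nchar(.data$seq) <= params$max_spacer_len) |>
    distinct(.data$seq, .data$full)
  if (nrow(distinct(spacers, .data$seq)) < params$min_spacers) return(NULL)
  tibble(consensus_repeat = canon, n_repeat_instances = n_inst,
         n_spacers = nrow(distinct(spacers, .data$seq)),
         spacers = list(spacers))
}

#' Merge spacer groups across read files and samples
#'
#' Groups whose consensus repeats are identical or reverse complements merge
#' into one (repeats are already stored on the lexicographically canonical
#' strand). Spacer lists are unioned with exact duplicates removed, partial
#' spacers that are substrings of a full spacer in the merged group are
#' absorbed, and sample provenance is retained per spacer.
#'
#' @param ... group tibbles from [extract_read_spacers()] /
#'   [rescue_known_repeats()].
#' @return a merged group tibble of the same shape.
#' @export
merge_groups <- function(...) {
  g <- bind_rows(...)
  if (nrow(g) == 0) return(empty_groups())
  g |>
    group_by(.data$consensus_repeat) |>
    summarise(
      sample_id = paste(sort(unique(.data$sample_id)), collapse = "+"),
      group_id = dplyr::first(.data$group_id),
      n_repeat_instances = sum(.data$n_repeat_instances),
      spacers = list({
        s <- distinct(bind_rows(.data$spacers),
                      .data$seq, .data$full, .data$sample_id)
        fulls <- unique(s$seq[s$full])
        drop <- !s$full & vapply(s$seq, function(p) {
          any(vapply(fulls, function(f) {
            grepl(p, f, fixed = TRUE) || grepl(revcomp(p), f, fixed = TRUE)
          }, logical(1)))
        }, logical(1))
        s[!drop, ]
      }),
      .groups = "drop"
    ) |>
    mutate(n_spacers = vapply(.data$spacers,
                              function(s) nrow(distinct(s, .data$seq)),
                              integer(1))) |>
    select("sample_id", "group_id", "consensus_repeat",
           "n_repeat_instances", "n_spacers", "spacers") |>
    arrange(.data$consensus_repeat)
}

#' Rescue spacers next to known repeats
#'
#' Reads containing an exact copy of a known repeat (either strand)
#' contribute their inter-repeat and flanking sequences as spacers, subject
#' to the usual `min_partial` filter — a targeted sweep for repeat families
#' the de novo pass missed.
#'
#' @param seqs character vector of read sequences.
#' @param known_repeats character vector of repeat sequences.
#' @param sample_id sample label.
#' @param min_partial minimum spacer length.
#' @return a group tibble (see [extract_read_spacers()]); groups here carry
#'   no minimum-instance filtering.
#' @export
rescue_known_repeats <- function(seqs, known_repeats, sample_id = "sample",
                                 min_partial = 16L) {
  if (!length(known_repeats)) abort("known_repeats must be non-empty")
  params <- read_spacer_params(min_repeats = 1L, min_spacers = 0L,
                               min_partial = min_partial)
  groups <- list()
  for (rep_seq in unique(canonical_strand(known_repeats))) {
    # reuse the group reader with the known repeat as a fixed consensus
    g <- read_group_for_repeat(seqs, rep_seq, params)
    if (!is.null(g)) groups[[length(groups) + 1L]] <- g
  }
  if (!length(groups)) return(empty_groups())
  out <- bind_rows(groups)
  out$sample_id <- sample_id
  out$group_id <- sprintf("%s_rescue%d", sample_id, seq_len(nrow(out)))
  out$spacers <- lapply(out$spacers, function(s) mutate(s, sample_id = sample_id))
  select(out, "sample_id", "group_id", "consensus_repeat",
         "n_repeat_instances", "n_spacers", "spacers")
}

read_group_for_repeat <- function(seqs, canon, params) {
  rlen <- nchar(canon)
  fwd <- locate_fixed(seqs, canon)
  rev_ <- if (canon != revcomp(canon)) locate_fixed(seqs, revcomp(canon)) else
    lapply(seqs, function(x) integer(0))
  sp <- list(); n_inst <- 0L
  for (i in seq_along(seqs)) {
    use_fwd <- length(fwd[[i]]) >= length(rev_[[i]])
    r <- if (use_fwd) seqs[i] else revcomp(seqs[i])
    p <- sort(if (use_fwd) fwd[[i]] else nchar(seqs[i]) - (rev_[[i]] + rlen))
    if (!length(p)) next
    n_inst <- n_inst + length(p)
    n <- nchar(r)
    if (length(p) > 1) {
      sp[[length(sp) + 1L]] <- tibble(seq = sub0(r, p[-length(p)] + rlen, p[-1]),
                                      full = TRUE)
    }
    flanks <- c(if (p[1] > 0) sub0(r, 0, p[1]),
                if (p[length(p)] + rlen < n) sub0(r, p[length(p)] + rlen, n))
    if (length(flanks)) sp[[length(sp) + 1L]] <- tibble(seq = flanks, full = FALSE)
  }
  if (n_inst < params$min_repeats || !length(sp)) return(NULL)
  spacers <- bind_rows(sp) |>
    filter(nchar(.data$seq) >= params$min_partial,
           nchar(.data$seq) <= params$max_spacer_len) |>
    distinct(.data$seq, .data$full)
  tibble(consensus_repeat = canon, n_repeat_instances = n_inst,
         n_spacers = nrow(distinct(spacers, .data$seq)),
         spacers = list(spacers))
}

#' Write read-spacer groups
#'
#' TSV of group summaries plus a spacer FASTA whose headers carry sample,
#' group and completeness.
#'
#' @param groups group tibble.
#' @param tsv_path,fasta_path output paths.
#' @export
write_groups <- function(groups, tsv_path, fasta_path) {
  readr::write_tsv(select(groups, -"spacers"), tsv_path)
  seqs <- character(0)
  for (i in seq_len(nrow(groups))) {
    s <- groups$spacers[[i]]
    if (!nrow(s)) next
    ids <- sprintf("%s|%s|spacer%d|%s", s$sample_id, groups$group_id[i],
                   seq_len(nrow(s)), ifelse(s$full, "full", "partial"))
    seqs[ids] <- s$seq
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, fasta_path, width = 70L)
  invisible(tsv_path)
}
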