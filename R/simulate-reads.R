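#' Generate a synthetic host decoy genome
#'
#' A random genome standing in for the eukaryotic host in mixed-community
#' read sets. Its only required property is non-homology to the community
#' genomes: candidates sharing any 31-mer (either strand) with a community
#' sequence are rejected and regenerated.
#'
#' @param length genome length in bp.
#' @param community optional character vector of community contig sequences
#'   to enforce non-homology against.
#' @param k k-mer size for the collision check.
#' @param max_tries regeneration attempts before giving up.
#' @return a single DNA string of class `character`.
#' @export
synth_host_genome <- function(length = 50000L, community = character(0),
                              k = 31L, max_tries = 10L) {
  comm_kmers <- if (length(community)) {
    unique(unlist(lapply(c(community, revcomp(community)), kmers, k = k)))
  } else character(0)
  for (i in seq_len(max_tries)) {
    g <- random_dna(length)
    if (!length(comm_kmers) || !any(kmers(g, k) %in% comm_kmers)) return(g)
  }
  abort("could not generate a host genome free of k-mer collisions")
}

#' Simulate paired reads from a mixed community
#'
#' Draws read pairs from a set of community genomes (by relative abundance)
#' and a host genome (at `host_fraction`), with uniform fragment placement,
#' random strand, and optional per-base substitution errors. Each pair's
#' origin is recorded, so host filtering and spacer recovery can be scored
#' against truth. At `error_rate = 0` every read is an exact substring (or
#' reverse complement) of its source genome.
#'
#' @param community named list of genomes; each genome is a named character
#'   vector of contig sequences (e.g. `panel$sequences`).
#' @param abundance named numeric vector of relative abundances (normalized
#'   internally); names match `community`.
#' @param host_genome host sequence (single string), or `NULL` for
#'   `host_fraction = 0`.
#' @param host_fraction probability a pair is host-derived.
#' @param read_len read length in bp (>= 50).
#' @param n_pairs number of read pairs.
#' @param error_rate per-base substitution probability.
#' @param insert_range fragment length range (uniform), at least
#'   `2 * read_len`.
#' @param seed integer seed.
#' @return a tibble with one row per pair: `read_id`, `seq1`, `seq2`,
#'   `source` (genome name or `"host"`), `contig`, `frag_start`, `frag_end`,
#'   `strand`, `is_host`.
#' @export
simulate_reads <- function(community, abundance = NULL, host_genome = NULL,
                           host_fraction = 0, read_len = 150L,
                           n_pairs = 1000L, error_rate = 0,
                           insert_range = NULL, seed = 1L) {
  if (read_len < 50) abort("read_len must be >= 50")
  if (host_fraction > 0 && is.null(host_genome)) {
    abort("host_fraction > 0 requires a host genome")
  }
  if (is.null(abundance)) {
    abundance <- setNames(rep(1, length(community)), names(community))
  }
  abundance <- abundance[names(community)] / sum(abundance[names(community)])
  if (is.null(insert_range)) insert_range <- c(2L * read_len, 2L * read_len + 100L)
  if (insert_range[1] < 2 * read_len) abort("insert must cover both reads")
  shortest <- min(vapply(community, function(g) min(nchar(g)), integer(1)),
                  if (!is.null(host_genome)) nchar(host_genome) else Inf)
  if (insert_range[2] > shortest) {
    abort("insert (and so read_len) is longer than the shortest contig")
  }

  withr::with_seed(seed, {
    is_host <- runif(n_pairs) < host_fraction
    src <- character(n_pairs)
    src[is_host] <- "host"
    n_comm <- sum(!is_host)
    src[!is_host] <- sample(names(community), n_comm, replace = TRUE,
                            prob = abundance)
    # pick contig proportional to length, then fragment
    contig <- character(n_pairs); fstart <- integer(n_pairs)
    flen <- sample(insert_range[1]:insert_range[2], n_pairs, replace = TRUE)
    strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
    seq1 <- character(n_pairs); seq2 <- character(n_pairs)
    genomes <- c(community, if (!is.null(host_genome)) {
      list(host = c(host = host_genome))
    })
    for (g in unique(src)) {
      idx <- which(src == g)
      ctgs <- genomes[[g]]
      ci <- sample(seq_along(ctgs), length(idx), replace = TRUE,
                   prob = nchar(ctgs))
      contig[idx] <- names(ctgs)[ci]
      clen <- nchar(ctgs)[ci]
      fl <- pmin(flen[idx], clen)
      s0 <- floor(runif(length(idx)) * (clen - fl + 1))
      fstart[idx] <- as.integer(s0)
      flen[idx] <- fl
      frag <- substring(ctgs[ci], s0 + 1, s0 + fl)
      fwd1 <- substr(frag, 1, read_len)
      fwd2 <- revcomp(substring(frag, fl - read_len + 1, fl))
      plus <- strand[idx] == "+"
      seq1[idx] <- ifelse(plus, fwd1, revcomp(substring(frag, fl - read_len + 1, fl)))
      seq2[idx] <- ifelse(plus, fwd2, revcomp(fwd1))
    }
    if (error_rate > 0) {
      seq1 <- vapply(seq1, mutate_seq, character(1), rate = error_rate,
                     USE.NAMES = FALSE)
      seq2 <- vapply(seq2, mutate_seq, character(1), rate = error_rate,
                     USE.NAMES = FALSE)
    }
    tibble(
      read_id = sprintf("read%06d", seq_len(n_pairs)),
      seq1 = seq1, seq2 = seq2, source = src, contig = contig,
      frag_start = fstart, frag_end = fstart + flen,
      strand = strand, is_host = is_host
    )
  })
}
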