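# Independent oracles used by the test suite. These deliberately do not share
# code with the implementation: textbook dynamic programming, exhaustive
# enumeration, per-base scans, and Biostrings-based matching.

## textbook Levenshtein DP
lev_dp <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  d <- matrix(0L, na + 1, nb + 1)
  d[, 1] <- 0:na; d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (av[i] != bv[j]))
    }
  }
  d[na + 1, nb + 1]
}

rc <- function(x) crisprcomb::revcomp(x)

## exhaustive hairpin search over all (arm5 start, arm3 start, arm length)
fold_hairpin_bruteforce <- function(seq, min_stem = 5L, min_loop = 3L) {
  n <- nchar(seq)
  best <- NULL
  for (i in 1:n) {
    for (L in min_stem:floor(n / 2)) {
      if (i + L - 1 > n) break
      arm5 <- substr(seq, i, i + L - 1)
      for (j in (i + L + min_loop):(n - L + 1)) {
        if (j < i + L + min_loop || j + L - 1 > n) next
        arm3 <- substr(seq, j, j + L - 1)
        if (arm3 != rc(arm5)) next
        loop <- j - (i + L - 1) - 1
        cand <- list(stem = L, loop = loop, i = i, j = j)
        if (is.null(best) || L > best$stem ||
            (L == best$stem && loop < best$loop) ||
            (L == best$stem && loop == best$loop && i < best$i)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(stem_len = best$stem,
       loop_seq = substr(seq, best$i + best$stem, best$j - 1))
}

## all-placements spacer matching oracle via Biostrings::matchPattern
match_oracle <- function(spacer, reference, min_identity = 0.80) {
  out <- list()
  for (tid in names(reference)) {
    subj <- Biostrings::DNAString(reference[[tid]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") spacer else rc(spacer)
      L <- nchar(q)
      mm <- L - ceiling(min_identity * L)
      hits <- Biostrings::matchPattern(Biostrings::DNAString(q), subj,
                                       max.mismatch = mm)
      st <- BiocGenerics::start(hits) - 1L
      if (length(st)) {
        out[[length(out) + 1L]] <- data.frame(target_id = tid, start = st,
                                              strand = strand)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(target_id = character(), start = integer(),
                      strand = character()))
  }
  do.call(rbind, out)
}

## per-base interval overlap oracle: does [s1,e1) (0-based) share a base with
## [s2,e2)?
overlaps_bruteforce <- function(s1, e1, s2, e2) {
  a <- seq.int(s1, length.out = max(0L, e1 - s1))
  b <- seq.int(s2, length.out = max(0L, e2 - s2))
  length(intersect(a, b)) > 0
}

## two-sided exact WMW p-value by full enumeration of labelings
wmw_enum_p <- function(x, y) {
  n1 <- length(x); z <- c(x, y); n <- length(z)
  Wstat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  w_obs <- Wstat(x, y)
  mu <- n1 * (n - n1) / 2
  sets <- utils::combn(n, n1)
  ws <- apply(sets, 2, function(ix) Wstat(z[ix], z[-ix]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

## a compact mixed panel used by several tests
make_test_panel <- function(seed = 101) {
  plans <- list(
    strain_plan("tA", contig_lengths = c(30000L, 18000L),
      arrays = list(
        array_plan("I-E", "canonical", n_spacers = 10, tetraloop = "TTCA",
                   spacer_sources = c(rep("random", 8),
                                      rep("prophage:ph1", 2)), contig = 1L),
        array_plan("I-E", "orphan", n_spacers = 8, tetraloop = "TTCG",
                   contig = 2L)
      ),
      prophages = list(prophage_plan("ph1", 5000L, "intact", contig = 1L)),
      genes = 2L),
    strain_plan("tB", contig_lengths = c(28000L),
      arrays = list(
        array_plan("II-C", "canonical", n_spacers = 7,
                   spacer_sources = c("shared:tA,1,1", "shared:tA,1,2",
                                      rep("random", 5)))
      ),
      prophages = list(prophage_plan("ph2", 4000L, "incomplete")),
      genes = 2L)
  )
  build_strain_panel(plans, seed = seed)
}
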