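test_that("host filtering keeps only pairs with both mates unmapped", {
  withr::with_seed(51, {
    host <- random_dna(3000)
    comm <- random_dna(3000)
    take <- function(src, at) substring(src, at, at + 99)
    reads <- tibble::tibble(
      read_id = c("hh", "hc", "cc"),
      seq1 = c(take(host, 101), take(host, 501), take(comm, 101)),
      seq2 = c(take(host, 1001), take(comm, 501), take(comm, 1001))
    )
    kept <- host_filter(reads, host)
    # both host -> removed; exactly one mate host -> removed; neither -> kept
    expect_identical(kept$read_id, "cc")
    expect_error(host_filter(tibble::tibble(seq1 = "ACGT"), host), "paired")
  })
})

test_that("a planted repeat-spacer-repeat read yields the spacer", {
  withr::with_seed(52, {
    R <- random_dna(23)
    S1 <- random_dna(32); S2 <- random_dna(32)
    reads <- c(
      paste0(random_dna(10), R, S1, R, random_dna(10)),
      paste0(random_dna(6), R, S2, R, random_dna(14)),
      paste0(R, S1, R, S2, R)
    )
    g <- extract_read_spacers(reads, sample_id = "m")
    expect_equal(nrow(g), 1L)
    expect_equal(g$consensus_repeat, crisprcomb:::canonical_strand(R))
    sp <- g$spacers[[1]]
    expect_setequal(crisprcomb:::canonical_strand(sp$seq[sp$full]),
                    crisprcomb:::canonical_strand(c(S1, S2)))
    # no spacer contains the group's repeat
    expect_false(any(grepl(g$consensus_repeat, sp$seq, fixed = TRUE)))
  })
})

pin_ends <- function(s, first, last) {
  substr(s, 1, 1) <- first
  substr(s, nchar(s), nchar(s)) <- last
  s
}

test_that("groups with fewer than two distinct spacers are discarded", {
  withr::with_seed(53, {
    R <- random_dna(23)
    S <- pin_ends(random_dna(32), "A", "A")
    # flanks end/start on bases distinct from the spacer ends, so the
    # repeat boundary is unambiguous by construction
    reads <- c(paste0(pin_ends(random_dna(8), "G", "C"), R, S, R,
                      pin_ends(random_dna(8), "G", "C")),
               paste0(pin_ends(random_dna(12), "T", "G"), R, S, R,
                      pin_ends(random_dna(4), "T", "G")))
    expect_equal(nrow(extract_read_spacers(reads)), 0L)
  })
})

test_that("short partial spacers at read ends are dropped", {
  withr::with_seed(54, {
    R <- random_dna(29)
    S1 <- pin_ends(random_dna(32), "A", "A")
    S2 <- pin_ends(random_dna(32), "C", "C")
    short_flank <- pin_ends(random_dna(15), "G", "G")  # < 16 bp: dropped
    long_flank <- pin_ends(random_dna(20), "T", "T")   # >= 16 bp: partial
    reads <- c(paste0(short_flank, R, S1, R, S2, R, long_flank))
    g <- extract_read_spacers(reads)
    sp <- g$spacers[[1]]
    canon <- crisprcomb:::canonical_strand
    expect_setequal(canon(sp$seq[sp$full]), canon(c(S1, S2)))
    expect_setequal(canon(sp$seq[!sp$full]), canon(long_flank))
  })
})

test_that("merge unifies identical and reverse-complement repeat groups", {
  withr::with_seed(55, {
    R <- random_dna(29)
    S1 <- pin_ends(random_dna(32), "A", "A")
    S2 <- pin_ends(random_dna(32), "C", "C")
    S3 <- pin_ends(random_dna(32), "G", "G")
    left <- c(paste0(R, S1, R, S2, R))
    right <- c(rc(paste0(R, S2, R, S3, R)))   # same array, other strand
    g1 <- extract_read_spacers(left, sample_id = "L")
    g2 <- extract_read_spacers(right, sample_id = "R")
    expect_equal(g1$consensus_repeat, g2$consensus_repeat)
    m <- merge_groups(g1, g2)
    expect_equal(nrow(m), 1L)
    sp <- m$spacers[[1]]
    expect_setequal(crisprcomb:::canonical_strand(unique(sp$seq[sp$full])),
                    crisprcomb:::canonical_strand(c(S1, S2, S3)))
    expect_setequal(unique(sp$sample_id), c("L", "R"))
    # disjoint repeats stay unmerged
    R2 <- random_dna(29)
    other <- extract_read_spacers(
      c(paste0(R2, random_dna(32), R2, random_dna(32), R2)),
      sample_id = "O")
    m2 <- merge_groups(g1, other)
    expect_equal(nrow(m2), 2L)
    # merging absorbs partials contained in full spacers
    part <- g1
    part$spacers <- list(tibble::tibble(seq = substr(S1, 1, 20),
                                        full = FALSE, sample_id = "P"))
    m3 <- merge_groups(g1, part)
    expect_false(substr(S1, 1, 20) %in%
                   m3$spacers[[1]]$seq[!m3$spacers[[1]]$full])
  })
})

test_that("rescue recovers flanking partial spacers around known repeats", {
  withr::with_seed(56, {
    R <- random_dna(29)
    flank20 <- random_dna(20)
    flank15 <- random_dna(15)
    reads <- c(paste0(R, flank20), paste0(flank15, R))
    g <- rescue_known_repeats(reads, R, sample_id = "q")
    expect_equal(nrow(g), 1L)
    expect_setequal(g$spacers[[1]]$seq, flank20)
    # reverse-complement reads contribute too
    g2 <- rescue_known_repeats(rc(reads), R, sample_id = "q")
    expect_setequal(g2$spacers[[1]]$seq, flank20)
    # no repeat-bearing reads -> empty
    expect_equal(nrow(rescue_known_repeats(c(random_dna(80)), R)), 0L)
    expect_error(rescue_known_repeats(reads, character(0)), "non-empty")
  })
})

test_that("simulated community reads recover the planted spacers", {
  plans <- list(
    strain_plan("rA", contig_lengths = 12000L,
      arrays = list(array_plan("I-E", "orphan", n_spacers = 10,
                               tetraloop = "TTCA")), genes = 1L),
    strain_plan("rB", contig_lengths = 12000L,
      arrays = list(array_plan("II-C", "canonical", n_spacers = 8)),
      genes = 1L)
  )
  panel <- build_strain_panel(plans, seed = 57)
  host <- withr::with_seed(57, synth_host_genome(
    15000L, community = unlist(panel$sequences, use.names = FALSE)))
  reads <- simulate_reads(panel$sequences, host_genome = host,
                          host_fraction = 0.25, n_pairs = 2400L, seed = 58)
  kept <- host_filter(reads, host)
  # every truth-labeled host pair is removed at error rate 0
  expect_false(any(kept$is_host))

  g <- merge_groups(extract_read_spacers(kept$seq1, "R1"),
                    extract_read_spacers(kept$seq2, "R2"))
  planted <- unlist(panel$truth$arrays$spacers)
  recovered <- unlist(lapply(g$spacers, function(s) s$seq[s$full]))
  expect_setequal(crisprcomb:::canonical_strand(unique(recovered)),
                  crisprcomb:::canonical_strand(unique(planted)))
})
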