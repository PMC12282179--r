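test_that("panel generation is deterministic and conserves planted counts", {
  p1 <- make_test_panel(seed = 101)
  p2 <- make_test_panel(seed = 101)
  expect_identical(p1$sequences, p2$sequences)
  expect_identical(p1$truth, p2$truth)
  p3 <- make_test_panel(seed = 102)
  expect_false(identical(p1$sequences, p3$sequences))

  expect_equal(nrow(p1$truth$arrays), 3L)
  expect_equal(sum(p1$truth$arrays$strain_id == "tA"), 2L)
  expect_equal(nrow(p1$prophages), 2L)
  # every planted feature appears exactly once
  expect_false(anyDuplicated(
    p1$truth$arrays[, c("contig_id", "start")]) > 0)
})

test_that("planted arrays reconstruct from truth coordinates", {
  panel <- make_test_panel()
  tr <- panel$truth$arrays
  for (i in seq_len(nrow(tr))) {
    ctg <- panel$sequences[[tr$strain_id[i]]][[tr$contig_id[i]]]
    units <- character(0)
    for (j in seq_len(tr$n_spacers[i])) {
      units <- c(units, tr$repeats[[i]][j], tr$spacers[[i]][j])
    }
    units <- c(units, tr$repeats[[i]][tr$n_spacers[i] + 1])
    expect_identical(substring(ctg, tr$start[i] + 1, tr$end[i]),
                     paste(units, collapse = ""))
  }
})

test_that("canonical/orphan placement respects the 500 bp rule", {
  panel <- make_test_panel()
  cg <- cas_genes(panel$genes)
  for (i in seq_len(nrow(panel$truth$arrays))) {
    a <- panel$truth$arrays[i, ]
    same <- cg[cg$contig_id == a$contig_id, ]
    nf <- nearest_feature(a$start, a$end, same)
    if (a$context == "canonical") {
      expect_lte(nf$gap, 500)
    } else {
      expect_true(is.na(nf$gap) || nf$gap > 500)
    }
  }
})

test_that("prophage-sourced spacers are exact copies at mutation rate 0", {
  panel <- make_test_panel()
  sp <- panel$truth$spacers
  pro <- sp[grepl("^prophage:", sp$source), ]
  expect_gt(nrow(pro), 0)
  for (i in seq_len(nrow(pro))) {
    pseq <- panel$prophage_seqs[[pro$prophage_id[i]]]
    hit <- grepl(pro$seq[i], pseq, fixed = TRUE) ||
      grepl(rc(pro$seq[i]), pseq, fixed = TRUE)
    expect_true(hit)
  }
})

test_that("mutated prophage spacers hit the binomial identity expectation", {
  rate <- 0.0625
  n_sp <- 1000L
  ids <- withr::with_seed(9, {
    vapply(seq_len(n_sp), function(i) {
      proto <- random_dna(32)
      mut <- crisprcomb:::mutate_seq(proto, rate)
      mean(strsplit(proto, "")[[1]] == strsplit(mut, "")[[1]])
    }, numeric(1))
  })
  # expected identity 1 - 0.0625 = 93.75%, empirical mean within +/- 1%
  expect_lt(abs(mean(ids) - 0.9375), 0.01)
})

test_that("overfull plans are rejected with a descriptive error", {
  plans <- list(strain_plan("bad", contig_lengths = 3000L,
    arrays = list(array_plan("I-E", "canonical", n_spacers = 10))))
  expect_error(build_strain_panel(plans, seed = 1), "exceed contig length")
})

test_that("shared spacers must reference already-generated donors", {
  plans <- list(strain_plan("solo", contig_lengths = 20000L,
    arrays = list(array_plan("I-E", "orphan", n_spacers = 2,
                             spacer_sources = c("shared:ghost,1,1", "random")))))
  expect_error(build_strain_panel(plans, seed = 1), "shared source")
})

test_that("read simulation respects origins, strands and host fraction", {
  panel <- make_test_panel()
  comm <- panel$sequences
  host <- withr::with_seed(5, synth_host_genome(
    20000L, community = unlist(comm, use.names = FALSE)))
  reads <- simulate_reads(comm, host_genome = host, host_fraction = 0.3,
                          n_pairs = 10000L, read_len = 100L, seed = 33)
  # binomial 99% interval for host fraction at n = 10,000
  p_hat <- mean(reads$is_host)
  expect_lt(abs(p_hat - 0.3), 2.576 * sqrt(0.3 * 0.7 / 10000))

  # error-free reads are exact substrings (or reverse complements)
  sub <- reads[sample.int(nrow(reads), 50), ]
  for (i in seq_len(nrow(sub))) {
    src <- if (sub$is_host[i]) c(host = host) else comm[[sub$source[i]]]
    ctg <- src[[sub$contig[i]]]
    found <- grepl(sub$seq1[i], ctg, fixed = TRUE) ||
      grepl(rc(sub$seq1[i]), ctg, fixed = TRUE)
    expect_true(found)
  }

  # boundary: host_fraction 0 labels nothing as host
  r0 <- simulate_reads(comm, host_fraction = 0, n_pairs = 50L, seed = 1)
  expect_false(any(r0$is_host))

  # reads longer than the shortest contig are rejected
  tiny <- list(t1 = c(c1 = random_dna(120)))
  expect_error(simulate_reads(tiny, n_pairs = 5L, read_len = 100L, seed = 1),
               "shortest contig")
})

test_that("panel files round-trip through the standard formats", {
  panel <- make_test_panel()
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  fa <- read_assembly(file.path(dir, "tA.fasta"))
  expect_identical(unname(fa), unname(panel$sequences$tA))
  # GFF coordinates come back 0-based half-open and equal truth
  genes <- read_gene_annotations(file.path(dir, "tA.gff3"))
  truth_genes <- panel$genes[panel$genes$strain_id == "tA", ]
  merged <- dplyr::inner_join(genes, truth_genes,
                              by = c("contig_id", "name"))
  expect_equal(nrow(merged), nrow(truth_genes))
  expect_equal(merged$start.x, merged$start.y)
  expect_equal(merged$end.x, merged$end.y)
  bed <- read_prophage_bed(file.path(dir, "prophages.bed"))
  expect_equal(nrow(bed), nrow(panel$prophages))
  expect_setequal(bed$completeness, panel$prophages$completeness)
})

test_that("fastq pairs round-trip", {
  reads <- tibble::tibble(read_id = c("r1", "r2"),
                          seq1 = c("ACGTACGTACGT", "TTTTGGGGCCCC"),
                          seq2 = c("GGGGTTTTAAAA", "ACACACACACAC"))
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a_1.fastq"); f2 <- file.path(dir, "a_2.fastq")
  write_paired_fastq(reads, f1, f2)
  back <- read_paired_fastq(f1, f2)
  expect_equal(back$seq1, reads$seq1)
  expect_equal(back$seq2, reads$seq2)
})
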