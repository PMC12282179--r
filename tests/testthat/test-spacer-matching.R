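test_that("dedupe collapses exact and reverse-complement duplicates", {
  s <- "ACGTACGTACGTACGTACGTACGTACGTACGT"
  tbl <- tibble::tibble(strain_id = "g1", seq = c(s, s))
  expect_equal(nrow(dedupe_spacers(tbl)), 1L)
  tbl2 <- tibble::tibble(strain_id = "g1", seq = c(s, rc(s)))
  expect_equal(nrow(dedupe_spacers(tbl2)), 1L)
  withr::with_seed(61, {
    distinct <- tibble::tibble(strain_id = "g1",
                               seq = vapply(1:5, function(i) random_dna(32),
                                            character(1)))
    expect_equal(nrow(dedupe_spacers(distinct)), 5L)
  })
})

mutate_at_positions <- function(s, pos) {
  for (i in pos) {
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), substr(s, i, i))[1]
  }
  s
}

test_that("identity thresholding keeps 6 substitutions and drops 7 (of 32)", {
  withr::with_seed(62, {
    sp <- random_dna(32)
    ref6 <- paste0(random_dna(500), mutate_at_positions(sp, seq(3, 28, 5)),
                   random_dna(500))
    ref7 <- paste0(random_dna(500), mutate_at_positions(sp, seq(2, 32, 5)),
                   random_dna(500))
    m6 <- match_spacers_to_reference(c(q = sp), c(r = ref6))
    expect_equal(nrow(m6), 1L)
    expect_equal(m6$identity, 100 * 26 / 32)
    expect_equal(m6$start, 500L)
    m7 <- match_spacers_to_reference(c(q = sp), c(r = ref7))
    expect_equal(nrow(m7), 0L)
  })
})

test_that("exact containment reports 100% with correct coordinates", {
  withr::with_seed(63, {
    sp <- random_dna(32)
    ref <- paste0(random_dna(300), sp, random_dna(200), rc(sp),
                  random_dna(100))
    m <- match_spacers_to_reference(c(q = sp), c(r = ref))
    exact <- m[m$identity == 100, ]
    expect_equal(nrow(exact), 2L)
    expect_setequal(exact$start, c(300L, 532L))
    expect_setequal(exact$strand, c("+", "-"))
  })
})

test_that("self-hits inside the source array interval are removed", {
  withr::with_seed(64, {
    sp <- random_dna(32)
    ref <- paste0(random_dna(200), sp, random_dna(200), sp, random_dna(100))
    spacers <- tibble::tibble(query_id = "q", seq = sp,
                              self_contig = "r", self_start = 190L,
                              self_end = 240L)
    m <- match_spacers_to_reference(spacers, c(r = ref))
    expect_false(any(m$start == 200L & m$strand == "+"))
    expect_true(any(m$start == 432L))
  })
})

test_that("matching equals the Biostrings placement oracle", {
  withr::with_seed(65, {
    ref <- c(c1 = random_dna(10000))
    spacers <- vapply(1:30, function(i) random_dna(32), character(1))
    # plant some degraded copies so hits exist
    for (i in 1:10) {
      at <- 300 * i
      copy <- mutate_at_positions(spacers[i], sample(1:32, sample(0:6, 1)))
      if (i %% 2 == 0) copy <- rc(copy)
      substr(ref[["c1"]], at, at + 31) <- copy
    }
    names(spacers) <- sprintf("q%02d", 1:30)
    got <- match_spacers_to_reference(spacers, ref)
    got_key <- sort(paste(got$query_id, got$target_id, got$start, got$strand))
    want_key <- sort(unlist(lapply(names(spacers), function(qid) {
      o <- match_oracle(spacers[[qid]], ref)
      if (nrow(o)) paste(qid, o$target_id, o$start, o$strand) else character(0)
    })))
    expect_identical(got_key, want_key)
  })
})

test_that("matching is strand-symmetric and monotone in the threshold", {
  withr::with_seed(66, {
    ref <- c(r = random_dna(3000))
    sp <- substring(ref[["r"]], 1001, 1032)
    sp <- mutate_at_positions(sp, c(4, 20))
    m_fwd <- match_spacers_to_reference(c(q = sp), ref)
    m_rev <- match_spacers_to_reference(c(q = sp), c(r = rc(ref[["r"]])))
    n <- nchar(ref[["r"]])
    expect_equal(nrow(m_rev), nrow(m_fwd))
    expect_setequal(n - m_rev$end, m_fwd$start)
    expect_setequal(sort(m_rev$identity), sort(m_fwd$identity))

    loose <- match_spacers_to_reference(c(q = sp), ref, min_identity = 0.75)
    strict <- match_spacers_to_reference(c(q = sp), ref, min_identity = 0.9)
    key <- function(m) paste(m$target_id, m$start, m$strand)
    expect_true(all(key(strict) %in% key(loose)))
    expect_error(match_spacers_to_reference(c(q = sp), ref, min_identity = 0.4),
                 "min_identity")
  })
})

test_that("gapped mode tolerates a small indel that ungapped misses", {
  withr::with_seed(67, {
    sp <- random_dna(32)
    target <- paste0(substr(sp, 1, 16), substr(sp, 18, 32))  # one deletion
    ref <- c(r = paste0(random_dna(200), target, random_dna(200)))
    ug <- match_spacers_to_reference(c(q = sp), ref)
    expect_equal(nrow(ug), 0L)
    gp <- match_spacers_to_reference(c(q = sp), ref, mode = "gapped")
    expect_gte(nrow(gp), 1L)
    expect_equal(max(gp$identity), 100 * 31 / 32)
  })
})

test_that("sharing matrix counts planted shared spacers in both directions", {
  withr::with_seed(68, {
    shared <- vapply(1:2, function(i) random_dna(32), character(1))
    a_only <- vapply(1:4, function(i) random_dna(32), character(1))
    b_only <- vapply(1:3, function(i) random_dna(32), character(1))
    tbl <- tibble::tibble(
      strain_id = c(rep("A", 6), rep("B", 5)),
      seq = c(shared, a_only, rc(shared[1]), shared[2], b_only)
    )
    sh <- sharing_matrix(tbl)
    cts <- sh$counts
    expect_equal(cts$n_shared[cts$query_strain == "A" &
                                cts$target_strain == "B"], 2L)
    expect_equal(cts$n_shared[cts$query_strain == "B" &
                                cts$target_strain == "A"], 2L)
    expect_equal(sh$totals$n_spacers, c(6L, 5L))

    # identical strains share everything
    dup <- tibble::tibble(strain_id = rep(c("X", "Y"), each = 4),
                          seq = rep(a_only, 2))
    shd <- sharing_matrix(dup)
    expect_true(all(shd$counts$n_shared == 4L))

    # disjoint random sets share nothing
    dis <- tibble::tibble(
      strain_id = rep(c("P", "Q"), each = 10),
      seq = vapply(1:20, function(i) random_dna(32), character(1)))
    expect_true(all(sharing_matrix(dis)$counts$n_shared == 0L))
    expect_error(sharing_matrix(dis[dis$strain_id == "P", ]), ">= 2 strains")
  })
})
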