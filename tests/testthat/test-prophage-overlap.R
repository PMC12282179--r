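mk_matches <- function(...) {
  m <- tibble::tibble(...)
  if (!"query_id" %in% names(m)) m$query_id <- sprintf("q%d", seq_len(nrow(m)))
  if (!"source_id" %in% names(m)) m$source_id <- "src"
  if (!"identity" %in% names(m)) m$identity <- 100
  m
}

test_that("padding extends by 32 bp each side and clips at bounds", {
  m <- mk_matches(target_id = "c1", start = c(100L, 10L), end = c(132L, 42L))
  p <- pad_intervals(m, contig_lengths = c(c1 = 150L))
  expect_equal(p$pad_start, c(68L, 0L))
  expect_equal(p$pad_end, c(150L, 74L))
  p0 <- pad_intervals(m, pad = 0L)
  expect_equal(p0$pad_start, m$start)
  expect_equal(p0$pad_end, m$end)
})

regions1 <- tibble::tibble(strain_id = "sB", contig_id = "c1",
                           start = 1000L, end = 3000L, prophage_id = "ph1",
                           completeness = "intact")

test_that("overlap counting honors the 1 bp rule and padding reach", {
  # padded interval ending exactly 1 bp inside the region: counted
  m1 <- pad_intervals(mk_matches(target_id = "c1", start = 937L, end = 969L))
  expect_true(count_prophage_overlaps(m1, regions1)$overlapping)
  # unpadded 30 bp short of the region: counted only thanks to padding
  m2 <- pad_intervals(mk_matches(target_id = "c1", start = 938L, end = 970L))
  expect_true(count_prophage_overlaps(m2, regions1)$overlapping)
  expect_false(count_prophage_overlaps(
    pad_intervals(mk_matches(target_id = "c1", start = 938L, end = 970L),
                  pad = 0L), regions1)$overlapping)
  # well clear of the region even after padding: not counted
  m3 <- pad_intervals(mk_matches(target_id = "c1", start = 100L, end = 132L))
  expect_false(count_prophage_overlaps(m3, regions1)$overlapping)
})

test_that("a padded match spanning two regions counts once per region", {
  two <- dplyr::bind_rows(
    regions1,
    dplyr::mutate(regions1, start = 3010L, end = 4000L, prophage_id = "ph2",
                  completeness = "questionable"))
  m <- pad_intervals(mk_matches(target_id = "c1", start = 2990L, end = 3022L))
  pc <- count_prophage_overlaps(m, two)
  expect_equal(pc$per_region$n_matches, c(1L, 1L))
  # questionable pools with incomplete in the edge class
  expect_setequal(pc$edges$completeness_class,
                  c("intact", "incomplete_or_questionable"))
})

test_that("edge summaries average unpadded identities", {
  m <- pad_intervals(mk_matches(target_id = "c1",
                                start = c(1100L, 1500L, 2000L),
                                end = c(1132L, 1532L, 2032L),
                                identity = c(100, 90, 95)))
  pc <- count_prophage_overlaps(m, regions1)
  expect_equal(pc$edges$n_matches, 3L)
  expect_equal(pc$edges$mean_identity, 95)
})

test_that("genic attribution partitions self, genic and intergenic", {
  arrays <- tibble::tibble(contig_id = "c1", start = 5000L, end = 5600L)
  genes <- tibble::tibble(contig_id = "c1", start = 7000L, end = 8000L,
                          type = "gene")
  m <- mk_matches(target_id = "c1",
                  start = c(5100L, 7500L, 9000L), end = c(5132L, 7532L, 9032L))
  ga <- genic_attribution(m, arrays, genes)
  expect_identical(ga$matches$category, c("self", "genic", "intergenic"))
  expect_equal(ga$summary$n_matches[ga$summary$category == "genic"], 1L)
})

test_that("attribution order is prophage first, then self, then genes", {
  arrays <- tibble::tibble(contig_id = "c1", start = 5000L, end = 5600L)
  genes <- tibble::tibble(contig_id = "c1", start = 7000L, end = 8000L,
                          type = "gene")
  m <- mk_matches(target_id = "c1",
                  start = c(1100L, 5100L, 7500L, 9000L),
                  end = c(1132L, 5132L, 7532L, 9032L))
  att <- attribute_matches(m, regions1, arrays, genes)
  expect_identical(sort(att$matches$category),
                   c("genic", "intergenic", "prophage", "self"))
  # partition: every match in exactly one category
  expect_equal(nrow(att$matches), nrow(m))
  expect_equal(sum(att$summary$n_matches), nrow(m))
})

test_that("overlap counts equal a per-base brute-force scan on random fixtures", {
  withr::with_seed(71, {
    for (i in 1:25) {
      n_m <- sample(3:12, 1); n_r <- sample(1:4, 1)
      m <- pad_intervals(mk_matches(
        target_id = "c1",
        start = as.integer(sample(0:5000, n_m))) |>
          dplyr::mutate(end = .data$start + 32L))
      reg <- tibble::tibble(
        strain_id = "s", contig_id = "c1",
        start = as.integer(sample(0:5000, n_r)),
        prophage_id = sprintf("p%d", seq_len(n_r)),
        completeness = sample(c("intact", "questionable", "incomplete"),
                              n_r, replace = TRUE))
      reg$end <- reg$start + as.integer(sample(100:1500, n_r, replace = TRUE))
      pc <- count_prophage_overlaps(m, reg)
      want <- vapply(seq_len(n_r), function(r) {
        sum(vapply(seq_len(n_m), function(j) {
          overlaps_bruteforce(m$pad_start[j], m$pad_end[j],
                              reg$start[r], reg$end[r])
        }, logical(1)))
      }, integer(1))
      expect_identical(pc$per_region$n_matches, want)
      want_any <- vapply(seq_len(n_m), function(j) {
        any(vapply(seq_len(n_r), function(r) {
          overlaps_bruteforce(m$pad_start[j], m$pad_end[j],
                              reg$start[r], reg$end[r])
        }, logical(1)))
      }, logical(1))
      expect_identical(pc$overlapping, want_any)
    }
  })
})

test_that("edge export writes deterministic per-class tables", {
  edges <- tibble::tibble(
    source_id = c("s1", "s1", "s2"), target_id = c("t1", "t2", "t1"),
    completeness_class = c("intact", "incomplete_or_questionable", "intact"),
    n_matches = c(3L, 1L, 2L), mean_identity = c(95, 88.5, 100))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- export_edges(edges, d1)
  p2 <- export_edges(edges, d2)
  expect_identical(readLines(p1[["intact"]]), readLines(p2[["intact"]]))
  got <- readr::read_tsv(p1[["intact"]], show_col_types = FALSE)
  expect_equal(got$n_matches, c(3L, 2L))
  # empty input still yields header-only files
  p3 <- export_edges(edges[0, ], withr::local_tempdir())
  expect_equal(length(readLines(p3[["intact"]])), 1L)
})
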