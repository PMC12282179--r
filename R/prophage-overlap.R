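## GRanges from a 0-based half-open tibble
as_granges0 <- function(x, seqlevels = NULL) {
  ctg <- if ("contig_id" %in% names(x)) x[["contig_id"]] else x[["target_id"]]
  GenomicRanges::GRanges(
    seqnames = factor(ctg, levels = seqlevels %||% unique(ctg)),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Pad match intervals
#'
#' Extends each match interval by `pad` bp on both sides (32 bp by default,
#' a buffer against imprecise region boundaries and strand error), clipped
#' at contig bounds when contig lengths are supplied.
#'
#' @param matches tibble with `target_id`, `start`, `end`.
#' @param pad bp added to each side.
#' @param contig_lengths optional named vector of contig lengths for
#'   right-clipping.
#' @return `matches` with added `pad_start`, `pad_end`.
#' @export
pad_intervals <- function(matches, pad = 32L, contig_lengths = NULL) {
  ps <- pmax(0L, matches$start - pad)
  pe <- matches$end + pad
  if (!is.null(contig_lengths)) {
    lim <- unname(contig_lengths[matches$target_id])
    pe <- pmin(pe, ifelse(is.na(lim), pe, lim))
  }
  mutate(matches, pad_start = as.integer(ps), pad_end = as.integer(pe))
}

completeness_class <- function(x) {
  ifelse(x == "intact", "intact", "incomplete_or_questionable")
}

#' Count spacer-match overlaps with prophage regions
#'
#' A padded match counts toward every prophage region it overlaps by at
#' least 1 bp (so a match spanning two adjacent regions counts once per
#' region). Per (source, target strain, completeness class) the match count
#' and mean unpadded identity are summarized, with questionable and
#' incomplete regions pooled.
#'
#' @param matches padded match tibble (see [pad_intervals()]) with
#'   `query_id`, `source_id`, `target_id`, `identity`.
#' @param regions prophage region tibble: `strain_id`, `contig_id`, `start`,
#'   `end`, `prophage_id`, `completeness`.
#' @return a list with `per_region` (counts per prophage region), `edges`
#'   (per source/target/completeness-class count and mean identity) and
#'   `overlapping` (logical vector: did each match hit any region).
#' @export
count_prophage_overlaps <- function(matches, regions) {
  if (!"pad_start" %in% names(matches)) {
    abort("matches must be padded first (see pad_intervals())")
  }
  if (nrow(matches) == 0 || nrow(regions) == 0) {
    return(list(
      per_region = mutate(regions, n_matches = 0L),
      edges = tibble(source_id = character(), target_id = character(),
                     completeness_class = character(), n_matches = integer(),
                     mean_identity = numeric()),
      overlapping = logical(nrow(matches))
    ))
  }
  lv <- unique(c(matches$target_id, regions$contig_id))
  mg <- as_granges0(tibble(contig_id = matches$target_id,
                           start = matches$pad_start, end = matches$pad_end),
                    seqlevels = lv)
  rg <- as_granges0(regions, seqlevels = lv)
  ov <- GenomicRanges::findOverlaps(mg, rg, minoverlap = 1L)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  per_region <- regions |>
    mutate(n_matches = as.integer(tabulate(sh, nbins = nrow(regions))))
  pairs <- tibble(
    source_id = matches$source_id[qh],
    target_id = regions$strain_id[sh],
    completeness_class = completeness_class(regions$completeness[sh]),
    identity = matches$identity[qh]
  )
  edges <- pairs |>
    group_by(.data$source_id, .data$target_id, .data$completeness_class) |>
    summarise(n_matches = n(), mean_identity = mean(.data$identity),
              .groups = "drop") |>
    arrange(.data$source_id, .data$target_id, .data$completeness_class)
  list(per_region = per_region, edges = edges,
       overlapping = seq_len(nrow(matches)) %in% qh)
}

#' Attribute non-prophage matches to genic or intergenic space
#'
#' Matches that overlap a CRISPR array interval are dropped as self-hits;
#' the remainder are genic when they overlap a gene feature, else
#' intergenic. Overlap is interval-only (strand ignored). Both unique-spacer
#' and total-match counts are reported per category.
#'
#' @param matches match tibble (unpadded coordinates are used) with
#'   `query_id`, `target_id`, `start`, `end`.
#' @param arrays array tibble (`contig_id`, `start`, `end`).
#' @param genes gene annotation tibble; only rows whose `type` is in
#'   `gene_types` are considered.
#' @param gene_types feature types counting as genes.
#' @return a list with `matches` (input rows plus `category` in
#'   `self`/`genic`/`intergenic`) and `summary` (per category: `n_matches`,
#'   `n_unique_spacers`).
#' @export
genic_attribution <- function(matches, arrays, genes, gene_types = "gene") {
  if (nrow(matches) == 0) {
    return(list(matches = mutate(matches, category = character(0)),
                summary = tibble(category = character(), n_matches = integer(),
                                 n_unique_spacers = integer())))
  }
  lv <- unique(c(matches$target_id, arrays$contig_id, genes$contig_id))
  mg <- as_granges0(tibble(contig_id = matches$target_id,
                           start = matches$start, end = matches$end),
                    seqlevels = lv)
  in_any <- function(tbl) {
    if (is.null(tbl) || nrow(tbl) == 0) return(logical(nrow(matches)))
    IRanges::overlapsAny(mg, as_granges0(tbl, seqlevels = lv),
                               minoverlap = 1L)
  }
  self <- in_any(arrays)
  genic <- in_any(filter(genes, .data$type %in% gene_types))
  category <- ifelse(self, "self", ifelse(genic, "genic", "intergenic"))
  out <- mutate(matches, category = category)
  list(
    matches = out,
    summary = out |>
      group_by(.data$category) |>
      summarise(n_matches = n(),
                n_unique_spacers = dplyr::n_distinct(.data$query_id),
                .groups = "drop")
  )
}

#' Attribute spacer matches end to end
#'
#' Runs the full attribution order: pad, count prophage overlaps, then pass
#' the unattributed remainder through array self-hit subtraction and
#' genic/intergenic intersection. Every retained match lands in exactly one
#' of prophage / self / genic / intergenic.
#'
#' @inheritParams count_prophage_overlaps
#' @inheritParams genic_attribution
#' @param pad,contig_lengths see [pad_intervals()].
#' @return a list with `matches` (category per match), `per_region`,
#'   `edges`, and `summary`.
#' @export
attribute_matches <- function(matches, regions, arrays, genes, pad = 32L,
                              contig_lengths = NULL, gene_types = "gene") {
  padded <- pad_intervals(matches, pad = pad, contig_lengths = contig_lengths)
  pc <- count_prophage_overlaps(padded, regions)
  rest <- padded[!pc$overlapping, ]
  ga <- genic_attribution(rest, arrays, genes, gene_types = gene_types)
  categorized <- bind_rows(
    mutate(padded[pc$overlapping, ], category = "prophage"),
    ga$matches
  )
  list(matches = categorized, per_region = pc$per_region, edges = pc$edges,
       summary = bind_rows(
         tibble(category = "prophage", n_matches = sum(pc$overlapping),
                n_unique_spacers = dplyr::n_distinct(
                  padded$query_id[pc$overlapping])),
         ga$summary
       ))
}

#' Export prophage edge tables
#'
#' Writes two tab-delimited edge tables, one for intact regions and one for
#' incomplete/questionable regions, with deterministic (source, target) row
#' order — the network-import companion files.
#'
#' @param edges edge tibble from [count_prophage_overlaps()].
#' @param dir output directory.
#' @return the two file paths, invisibly.
#' @export
export_edges <- function(edges, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(intact = file.path(dir, "edges_intact.tsv"),
             incomplete_or_questionable =
               file.path(dir, "edges_incomplete_questionable.tsv"))
  for (cls in names(paths)) {
    e <- edges |>
      filter(.data$completeness_class == cls) |>
      select("source_id", "target_id", "n_matches", "mean_identity") |>
      arrange(.data$source_id, .data$target_id)
    readr::write_tsv(e, paths[[cls]])
  }
  invisible(paths)
}
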