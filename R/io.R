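#' Read and write the pipeline's file formats
#'
#' FASTA and FASTQ go through Biostrings; GFF3 through rtracklayer (coordinates
#' converted to 0-based half-open on read, back to 1-based inclusive on write).
#' Prophage regions use a 7-column BED variant whose extra column carries the
#' completeness label (`intact`, `questionable`, `incomplete`).
#'
#' @name crispr_io
NULL

#' @rdname crispr_io
#' @param path file path.
#' @return `read_assembly()`: a named character vector of contig sequences.
#' @export
read_assembly <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(out))) abort("duplicate contig ids in assembly")
  out
}

#' @rdname crispr_io
#' @param seqs named character vector of sequences.
#' @export
write_assembly <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname crispr_io
#' @return `read_gene_annotations()`: a tibble with columns `contig_id`,
#'   `start`, `end` (0-based half-open), `strand`, `type`, `name`.
#' @export
read_gene_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  nm <- S4Vectors::mcols(gr)$Name
  if (is.null(nm)) nm <- S4Vectors::mcols(gr)$ID
  tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start     = GenomicRanges::start(gr) - 1L,
    end       = GenomicRanges::end(gr),
    strand    = as.character(GenomicRanges::strand(gr)),
    type      = as.character(S4Vectors::mcols(gr)$type),
    name      = as.character(nm %||% NA_character_)
  )
}

#' @rdname crispr_io
#' @param genes tibble with `contig_id`, `start`, `end`, `strand`, `type`,
#'   `name` (0-based half-open).
#' @export
write_gene_annotations <- function(genes, path) {
  strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = strand
  )
  S4Vectors::mcols(gr)$type <- genes$type
  S4Vectors::mcols(gr)$ID <- paste0("feat", seq_len(nrow(genes)))
  S4Vectors::mcols(gr)$Name <- genes$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname crispr_io
#' @return `read_prophage_bed()`: a tibble with `contig_id`, `start`, `end`,
#'   `prophage_id`, `completeness` (plus `strain_id` if encoded in the name).
#' @export
read_prophage_bed <- function(path) {
  cols <- readr::cols(
    X1 = readr::col_character(), X2 = readr::col_integer(),
    X3 = readr::col_integer(), X4 = readr::col_character(),
    X5 = readr::col_character(), X6 = readr::col_character(),
    X7 = readr::col_character()
  )
  x <- readr::read_tsv(path, col_names = FALSE, col_types = cols,
                       progress = FALSE)
  tibble(
    contig_id = x$X1, start = x$X2, end = x$X3,
    prophage_id = x$X4, completeness = x$X7
  )
}

#' @rdname crispr_io
#' @param regions tibble with `contig_id`, `start`, `end`, `prophage_id`,
#'   `completeness`.
#' @export
write_prophage_bed <- function(regions, path) {
  out <- data.frame(
    regions$contig_id, regions$start, regions$end, regions$prophage_id,
    0L, ".", regions$completeness
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname crispr_io
#' @return `read_paired_fastq()`: a tibble with `read_id`, `seq1`, `seq2`.
#' @param path1,path2 mate FASTQ files.
#' @export
read_paired_fastq <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(r1) != length(r2)) abort("unpaired input: mate files differ in length")
  tibble(
    read_id = sub("/[12]$", "", sub("\\s.*$", "", names(r1))),
    seq1 = unname(as.character(r1)),
    seq2 = unname(as.character(r2))
  )
}

#' @rdname crispr_io
#' @param reads tibble with `read_id`, `seq1`, `seq2`.
#' @param qual constant phred quality character applied to every base.
#' @export
write_paired_fastq <- function(reads, path1, path2, qual = "I") {
  wr <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(strrep(qual, nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  wr(reads$seq1, paste0(reads$read_id, "/1"), path1)
  wr(reads$seq2, paste0(reads$read_id, "/2"), path2)
  invisible(c(path1, path2))
}

#' Write spacers and repeats in bulk
#'
#' Emits a FASTA of spacers (and optionally repeats) with systematic ids of
#' the form `strain|contig|arrayN|spacerM`, for cross-genome matching.
#'
#' @param arrays an array tibble as returned by [strain_scan()].
#' @param path output FASTA path.
#' @param what `"spacers"` or `"repeats"`.
#' @return the path, invisibly.
#' @export
write_array_fasta <- function(arrays, path, what = c("spacers", "repeats")) {
  what <- match.arg(what)
  seqs <- character(0)
  for (i in seq_len(nrow(arrays))) {
    units <- arrays[[what]][[i]]
    if (length(units) == 0) next
    ids <- sprintf("%s|%s|array%d|%s%d",
                   arrays$strain_id[i], arrays$contig_id[i],
                   arrays$array_idx[i] %||% i,
                   sub("s$", "", what), seq_along(units))
    seqs[ids] <- units
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
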