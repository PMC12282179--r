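#' DNA string helpers
#'
#' Small utilities used throughout the package. Sequences are plain upper-case
#' character strings over ACGT (N permitted where stated); coordinates are
#' 0-based half-open everywhere inside the package.
#'
#' @param x character vector of DNA strings.
#' @return `revcomp()` returns the reverse complement of each element.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

DNA_BASES <- c("A", "C", "G", "T")

#' Generate random DNA
#'
#' Uniform i.i.d. bases; draws come from the current RNG stream so callers
#' control determinism with a single seed.
#'
#' @param n length in bp.
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## canonical strand form: lexicographic minimum of a sequence and its
## reverse complement
canonical_strand <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

## all k-mers of a string as a character vector (positions 0-based on request)
kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

assert_dna <- function(seq, allow_n = TRUE, arg = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!all(grepl(pat, seq))) {
    abort(sprintf("%s contains characters outside %s", arg,
                  if (allow_n) "ACGTN" else "ACGT"))
  }
  invisible(seq)
}

## substring by 0-based half-open coordinates
sub0 <- function(seq, start, end) substring(seq, start + 1, end)

## per-base substitution mutations at a fixed rate; substitutions only
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1)
    }, character(1))
  }
  paste(bases, collapse = "")
}

## ungapped identity between two equal-length strings: matches / length
ungapped_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  mean(av == bv)
}

## Levenshtein distance via base R's generalized edit distance
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

## minimum gap between two 0-based half-open intervals; 0 on overlap/abutment
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1, s1 - e2))
}
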