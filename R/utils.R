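#' Percentage of a count, rounded to two decimals
#'
#' The package reports all headline fractions (group shares, responsive-target
#' fractions, uORF gene fractions) as `100 * n / total` rounded to two
#' decimals; this helper is that single definition.
#'
#' @param n Count (numerator), non-negative.
#' @param total Count (denominator), positive.
#' @return Numeric percentage rounded to 2 decimals.
#' @examples
#' percent_of(71, 318) # 22.33
#' @export
percent_of <- function(n, total) {
  stopifnot(is.numeric(n), is.numeric(total))
  if (any(total <= 0)) abort("`total` must be positive.")
  if (any(n < 0)) abort("`n` must be non-negative.")
  round(100 * n / total, 2)
}

# GFF3 1-based closed -> internal 0-based half-open
gff_to_zero <- function(start1, end1) {
  list(start = start1 - 1L, end = end1)
}

# internal 0-based half-open -> GFF3 1-based closed
zero_to_gff <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

# tibble of intervals -> IRanges (0-based half-open in, 1-based closed out)
intervals_to_iranges <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

# GRanges constructor from 0-based half-open tibble columns
make_granges <- function(chrom, start0, end0, strand = NULL, ...) {
  if (length(chrom) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = if (is.null(strand)) "*" else strand,
    ...
  )
}

granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# strict integerish check for count tables
is_whole <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(abs(x - round(x)) < 1e-9)
}

valid_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  all(grepl(pat, x))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
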