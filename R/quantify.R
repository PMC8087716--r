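#' Compute FPKM from a count table
#'
#' `fpkm = count * 1e9 / (length_nt * library_size)`. By default the
#' library size of a sample is its column sum within the supplied table
#' (self-contained normalization); externally determined totals (e.g.
#' aligner-reported mapped reads) can be supplied instead.
#'
#' @param counts Tibble with `feature_id` plus one integer column per sample.
#' @param lengths Feature lengths in nt: a named numeric vector or a tibble
#'   with `feature_id` and `length_nt`.
#' @param library_sizes Optional named numeric vector of per-sample library
#'   sizes overriding the column sums.
#' @return Tibble of the same shape as `counts` holding FPKM values.
#' @examples
#' counts <- tibble::tibble(feature_id = "g1", s1 = 10L)
#' compute_fpkm(counts, c(g1 = 1000), library_sizes = c(s1 = 1e6)) # 10
#' @export
compute_fpkm <- function(counts, lengths, library_sizes = NULL) {
  stopifnot("feature_id" %in% names(counts))
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length_nt, lengths$feature_id)
  }
  len <- lengths[counts$feature_id]
  if (anyNA(len)) abort("length missing for some features")
  if (any(len <= 0)) abort("feature lengths must be positive")
  out <- counts
  for (s in setdiff(names(counts), "feature_id")) {
    lib <- if (is.null(library_sizes)) sum(counts[[s]]) else library_sizes[[s]]
    if (is.null(lib) || is.na(lib) || lib <= 0) {
      abort(sprintf("library size for sample '%s' is zero or missing", s))
    }
    out[[s]] <- unname(counts[[s]] * 1e9 / (len * lib))
  }
  out
}

#' Per-condition mean FPKM and translational efficiency
#'
#' TE is the ratio of the condition-mean ribosome-footprint FPKM to the
#' condition-mean RNA FPKM. TE is undefined (NA) when the RNA mean is below
#' `min_rna_fpkm`; it is never infinite.
#'
#' @param fpkm_rna,fpkm_ribo FPKM tibbles from [compute_fpkm()] (`feature_id`
#'   plus sample columns), sharing gene identifiers.
#' @param samples Sample sheet tibble (`sample`, `condition`, `replicate`)
#'   covering the columns of both tables.
#' @param min_rna_fpkm RNA expression filter (default 1).
#' @return Tibble `gene_id`, `condition`, `mean_fpkm_rna`, `mean_fpkm_ribo`,
#'   `te`.
#' @export
compute_te <- function(fpkm_rna, fpkm_ribo, samples, min_rna_fpkm = 1) {
  cond_means <- function(fpkm, value_name) {
    tidyr::pivot_longer(fpkm, -"feature_id", names_to = "sample",
                        values_to = "fpkm") |>
      inner_join(samples, by = "sample") |>
      group_by(gene_id = .data$feature_id, condition = .data$condition) |>
      summarise("{value_name}" := mean(.data$fpkm), .groups = "drop")
  }
  inner_join(cond_means(fpkm_rna, "mean_fpkm_rna"),
             cond_means(fpkm_ribo, "mean_fpkm_ribo"),
             by = c("gene_id", "condition")) |>
    mutate(te = if_else(.data$mean_fpkm_rna >= min_rna_fpkm,
                        .data$mean_fpkm_ribo / .data$mean_fpkm_rna,
                        NA_real_))
}

# P-site proxy positions (0-based genomic) for a footprint table
psite_positions <- function(reads, psite_offset) {
  if (any(psite_offset >= reads$length)) {
    abort("P-site offset must be smaller than every read length")
  }
  ifelse(reads$strand == "+",
         reads$five_prime + psite_offset,
         reads$five_prime - psite_offset)
}

#' Assign ribosome footprints to transcript feature categories
#'
#' Each read is represented by its P-site proxy (5' end plus a fixed offset
#' in transcript orientation, i.e. along the gene strand) and assigned to
#' the single category containing that position, with priority
#' 5' UTR > CDS > 3' UTR > intron. Reads whose P-site falls outside every
#' annotated transcript are dropped and counted separately; fractions are
#' over assigned reads and sum to 1.
#'
#' @param reads Tibble with `chrom`, `strand`, `five_prime` (0-based
#'   position of the read 5' end) and `length`.
#' @param models Gene-model tibble.
#' @param psite_offset Offset from the read 5' end to the P-site proxy,
#'   default 12 nt (conventional for ~32-nt footprints).
#' @return Tibble `category`, `n`, `fraction` (categories `utr5`, `cds`,
#'   `utr3`, `intron`), with the number of unassigned reads in attribute
#'   `unassigned`.
#' @export
assign_reads_to_features <- function(reads, models, psite_offset = 12L) {
  if (nrow(reads) == 0L) abort("no reads supplied")
  ps <- psite_positions(reads, psite_offset)
  q <- make_granges(reads$chrom, ps, ps + 1L)

  cat_ranges <- function(col) {
    tbls <- purrr::map2(models[[col]], seq_len(nrow(models)), function(t, i) {
      if (nrow(t) == 0L) return(NULL)
      mutate(t, chrom = models$chrom[i])
    })
    tbl <- bind_rows(tbls)
    if (is.null(tbl) || nrow(tbl) == 0L) {
      return(GenomicRanges::GRanges())
    }
    make_granges(tbl$chrom, tbl$start, tbl$end)
  }
  utr5 <- cat_ranges("utr5")
  cds <- cat_ranges("cds")
  utr3 <- cat_ranges("utr3")
  # introns: gene span minus exons
  span <- make_granges(models$chrom, models$start, models$end)
  exons <- cat_ranges("exons")
  intron <- GenomicRanges::setdiff(span, exons)

  assigned <- rep(NA_character_, nrow(reads))
  for (nm in c("intron", "utr3", "cds", "utr5")) { # reverse priority
    subj <- switch(nm, utr5 = utr5, cds = cds, utr3 = utr3, intron = intron)
    if (length(subj) == 0L) next
    hit <- IRanges::overlapsAny(q, subj)
    assigned[hit] <- nm
  }
  n_unassigned <- sum(is.na(assigned))
  tab <- table(factor(assigned, levels = c("utr5", "cds", "utr3", "intron")))
  out <- tibble(category = names(tab), n = as.integer(tab),
                fraction = as.integer(tab) / sum(tab))
  attr(out, "unassigned") <- n_unassigned
  out
}

#' Count footprint P-sites per interval and sample
#'
#' @param reads Footprint tibble with `chrom`, `strand`, `five_prime`,
#'   `length` and `sample`.
#' @param intervals Tibble with `id`, `chrom`, `start`, `end` (0-based
#'   half-open); rows with duplicate `id` (e.g. spliced parts) are summed.
#' @param psite_offset P-site offset, default 12.
#' @return Tibble `feature_id` plus one count column per sample present in
#'   `reads`.
#' @export
count_psites <- function(reads, intervals, psite_offset = 12L) {
  ps <- psite_positions(reads, psite_offset)
  q <- make_granges(reads$chrom, ps, ps + 1L)
  subj <- make_granges(intervals$chrom, intervals$start, intervals$end)
  hits <- GenomicRanges::findOverlaps(q, subj)
  smp <- sort(unique(reads$sample))
  ids <- unique(intervals$id)
  out <- matrix(0L, nrow = length(ids), ncol = length(smp),
                dimnames = list(ids, smp))
  if (length(hits)) {
    hit_id <- intervals$id[S4Vectors::subjectHits(hits)]
    hit_smp <- reads$sample[S4Vectors::queryHits(hits)]
    tab <- table(factor(hit_id, levels = ids), factor(hit_smp, levels = smp))
    out <- out + unclass(tab)
  }
  bind_cols(tibble(feature_id = ids), as_tibble(as.data.frame.matrix(out)))
}

#' Footprint length histogram and modal length
#'
#' @param reads Footprint tibble with a `length` column (or a bare numeric
#'   vector of lengths).
#' @return Tibble `length`, `n` sorted by length, with the modal length in
#'   attribute `modal_length`; ties break toward the smaller length.
#' @export
rf_length_distribution <- function(reads) {
  lens <- if (is.data.frame(reads)) reads$length else reads
  if (length(lens) == 0L) abort("no footprint lengths supplied")
  if (any(lens <= 0)) abort("footprint lengths must be positive")
  tab <- table(lens)
  out <- tibble(length = as.integer(names(tab)), n = as.integer(tab)) |>
    arrange(.data$length)
  attr(out, "modal_length") <- out$length[which.max(out$n)]
  out
}

#' Modal footprint length
#'
#' @inheritParams rf_length_distribution
#' @return Integer modal length (ties toward the smaller length).
#' @export
rf_modal_length <- function(reads) {
  attr(rf_length_distribution(reads), "modal_length")
}
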