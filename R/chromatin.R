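#' Reproducible THSs from replicate peak sets
#'
#' A reported transposase hypersensitive site (THS) is the union of a
#' connected chain of replicate peaks in which at least one genomic
#' position is covered by a peak from every replicate; chains lacking
#' all-replicate support are dropped.
#'
#' @param peaks Peak tibble with `chrom`, `start`, `end`, `replicate`
#'   (0-based half-open), all replicates of one condition.
#' @param n_replicates Number of replicates expected; defaults to the
#'   number of distinct `replicate` values present.
#' @return Tibble `ths_id`, `chrom`, `start`, `end`, `n_replicates`.
#' @export
reproducible_ths <- function(peaks, n_replicates = NULL) {
  if (nrow(peaks) == 0L) {
    warn("empty replicate peak set; returning empty THS set")
    return(tibble(ths_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  n_replicates = integer()))
  }
  reps <- sort(unique(peaks$replicate))
  n_rep <- n_replicates %||% length(reps)
  all_gr <- make_granges(peaks$chrom, peaks$start, peaks$end)
  clusters <- GenomicRanges::reduce(all_gr)
  per_rep <- purrr::map(reps, function(r) {
    sub <- peaks[peaks$replicate == r, , drop = FALSE]
    GenomicRanges::reduce(make_granges(sub$chrom, sub$start, sub$end))
  })
  # replicates may cover different chromosome sets; seqlevel-union
  # warnings from the intersection are expected and meaningless here
  common <- suppressWarnings(Reduce(GenomicRanges::intersect, per_rep))
  keep <- suppressWarnings(IRanges::overlapsAny(clusters, common)) &
    rep(length(reps) == n_rep, length(clusters))
  ths <- clusters[keep]
  out <- arrange(granges_to_tbl(ths), .data$chrom, .data$start)
  out$ths_id <- sprintf("THS_%04d", seq_len(nrow(out)))
  out$n_replicates <- n_rep
  select(out, "ths_id", "chrom", "start", "end", "n_replicates")
}

#' Overlap between two condition THS sets
#'
#' Counts THSs shared between conditions at a minimum overlap of
#' `min_overlap` bp, per set (a CK THS is shared when it overlaps any LT
#' THS and vice versa), so `shared_ck + ck_only = |CK|` and
#' `shared_lt + lt_only = |LT|`.
#'
#' @param ths_ck,ths_lt THS tibbles (`chrom`, `start`, `end`).
#' @param min_overlap Minimum intersection in bp (default 1).
#' @return Tibble with `set` and `n` rows `ck_total`, `lt_total`,
#'   `shared_ck`, `shared_lt`, `ck_only`, `lt_only`.
#' @export
condition_overlap <- function(ths_ck, ths_lt, min_overlap = 1L) {
  gr_ck <- make_granges(ths_ck$chrom, ths_ck$start, ths_ck$end)
  gr_lt <- make_granges(ths_lt$chrom, ths_lt$start, ths_lt$end)
  sh_ck <- sum(IRanges::overlapsAny(gr_ck, gr_lt, minoverlap = min_overlap))
  sh_lt <- sum(IRanges::overlapsAny(gr_lt, gr_ck, minoverlap = min_overlap))
  tibble(
    set = c("ck_total", "lt_total", "shared_ck", "shared_lt",
            "ck_only", "lt_only"),
    n = c(nrow(ths_ck), nrow(ths_lt), sh_ck, sh_lt,
          nrow(ths_ck) - sh_ck, nrow(ths_lt) - sh_lt)
  )
}

# promoter windows (0-based half-open) upstream of each TSS in gene
# orientation
promoter_windows <- function(models, promoter_bp) {
  mutate(models[, c("gene_id", "chrom", "strand", "tss")],
         start = if_else(.data$strand == "+",
                         pmax(.data$tss - as.integer(promoter_bp), 0L),
                         .data$tss + 1L),
         end = if_else(.data$strand == "+",
                       .data$tss,
                       .data$tss + 1L + as.integer(promoter_bp)))
}

#' Annotate THSs by genomic context
#'
#' Classifies each THS by its midpoint with priority
#' promoter > exon > intron > distal intergenic; the promoter is the
#' `promoter_bp` window upstream of a TSS in the gene's orientation. The
#' nearest gene (by TSS distance) and the signed midpoint-to-TSS distance
#' (negative = upstream of the TSS in the gene's orientation) are always
#' reported; THSs on chromosomes absent from the annotation are
#' `distal_intergenic` with an undefined nearest gene.
#'
#' @param ths THS tibble (`ths_id`, `chrom`, `start`, `end`).
#' @param models Gene-model tibble.
#' @param promoter_bp Promoter window size upstream of the TSS (default
#'   2000).
#' @return Input with `midpoint`, `category`, `nearest_gene_id`,
#'   `distance_to_tss` and `is_distal` columns added.
#' @export
annotate_ths <- function(ths, models, promoter_bp = 2000L) {
  mid <- (ths$start + ths$end) %/% 2L
  prom <- promoter_windows(models, promoter_bp)
  prom <- prom[prom$end > prom$start, , drop = FALSE]
  prom_gr <- make_granges(prom$chrom, prom$start, prom$end)
  exon_tbl <- bind_rows(purrr::map(seq_len(nrow(models)), function(i) {
    t <- models$exons[[i]]
    if (nrow(t) == 0L) return(NULL)
    mutate(t, chrom = models$chrom[i])
  }))
  exon_gr <- if (nrow(exon_tbl %||% tibble())) {
    make_granges(exon_tbl$chrom, exon_tbl$start, exon_tbl$end)
  } else GenomicRanges::GRanges()
  span_gr <- make_granges(models$chrom, models$start, models$end)
  mid_gr <- make_granges(ths$chrom, mid, mid + 1L)

  in_prom <- suppressWarnings(IRanges::overlapsAny(mid_gr, prom_gr))
  in_exon <- suppressWarnings(IRanges::overlapsAny(mid_gr, exon_gr))
  in_span <- suppressWarnings(IRanges::overlapsAny(mid_gr, span_gr))
  category <- dplyr::case_when(
    in_prom ~ "promoter",
    in_exon ~ "exon",
    in_span ~ "intron",
    TRUE ~ "distal_intergenic"
  )

  nearest_gene <- rep(NA_character_, nrow(ths))
  dist_tss <- rep(NA_real_, nrow(ths))
  for (i in seq_len(nrow(ths))) {
    g <- models[models$chrom == ths$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    d_abs <- abs(mid[i] - g$tss)
    j <- order(d_abs, g$gene_id)[1]
    nearest_gene[i] <- g$gene_id[j]
    dist_tss[i] <- if (g$strand[j] == "+") mid[i] - g$tss[j]
                   else g$tss[j] - mid[i]
  }

  mutate(ths, midpoint = mid, category = category,
         nearest_gene_id = nearest_gene, distance_to_tss = dist_tss,
         is_distal = category == "distal_intergenic")
}

#' Call cold-induced THSs
#'
#' An LT THS is cold-induced when (a) it has no overlap (>= 1 bp) with any
#' CK reproducible THS, (b) the |log2 fold change| of library-size
#' normalized read counts (LT vs CK, pseudocount 1 on CPM) is at least
#' `log2(fc_threshold)`, and (c) a Welch t-test on the log2-normalized
#' counts gives `p < p_threshold`. Candidates without count support are
#' skipped with a warning.
#'
#' @param ths_lt LT reproducible THS tibble (`ths_id`, `chrom`, `start`,
#'   `end`).
#' @param ths_ck CK reproducible THS tibble.
#' @param peak_counts Tibble `chrom`, `start`, `end` plus one read-count
#'   column per sample (all six samples).
#' @param samples Sample sheet tibble.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param p_threshold p-value threshold (default 0.05).
#' @return LT-only candidate tibble with `log2fc`, `p` and logical
#'   `cold_induced` columns.
#' @export
cold_induced_ths <- function(ths_lt, ths_ck, peak_counts, samples,
                             fc_threshold = 2, p_threshold = 0.05) {
  gr_lt <- make_granges(ths_lt$chrom, ths_lt$start, ths_lt$end)
  gr_ck <- make_granges(ths_ck$chrom, ths_ck$start, ths_ck$end)
  lt_only <- ths_lt[!suppressWarnings(IRanges::overlapsAny(gr_lt, gr_ck)), ,
                    drop = FALSE]
  if (nrow(lt_only) == 0L) {
    return(mutate(lt_only, log2fc = numeric(0), p = numeric(0),
                  cold_induced = logical(0)))
  }
  smp <- samples$sample
  cnt_mat <- as.matrix(peak_counts[, smp, drop = FALSE])
  libs <- colSums(cnt_mat)
  if (any(libs == 0)) abort("zero library size in peak counts")
  # composition-robust per-sample scaling (median-of-ratios, column sums
  # as fallback for tiny tables), expressed on a counts-per-million scale
  sf <- suppressWarnings(
    estimate_size_factors(bind_cols(tibble(feature_id = as.character(
      seq_len(nrow(peak_counts)))), as_tibble(cnt_mat))))
  eff_lib <- sf * exp(mean(log(libs)))
  cpm <- sweep(cnt_mat, 2, eff_lib / 1e6, "/")
  cnt_gr <- make_granges(peak_counts$chrom, peak_counts$start,
                         peak_counts$end)
  cand_gr <- make_granges(lt_only$chrom, lt_only$start, lt_only$end)
  ov <- GenomicRanges::findOverlaps(cand_gr, cnt_gr)

  ck_samples <- samples$sample[samples$condition == "CK"]
  lt_samples <- samples$sample[samples$condition != "CK"]
  res <- purrr::map(seq_len(nrow(lt_only)), function(i) {
    rows <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    if (length(rows) == 0L) {
      warn(sprintf("no read counts overlap THS %s; skipped",
                   lt_only$ths_id[i]))
      return(tibble(log2fc = NA_real_, p = NA_real_, cold_induced = NA))
    }
    v <- colSums(cpm[rows, , drop = FALSE])
    lfc <- log2_fold_change(mean(v[lt_samples]), mean(v[ck_samples]))
    tt <- welch_t_test(log2(v[lt_samples] + 1), log2(v[ck_samples] + 1))
    tibble(log2fc = lfc, p = tt$p,
           cold_induced = abs(lfc) >= log2(fc_threshold) &
             tt$p < p_threshold)
  })
  bind_cols(lt_only, bind_rows(res))
}

#' Assign target genes to distal THSs
#'
#' The target is the closest downstream gene: among genes for which the
#' THS midpoint lies upstream of the TSS in the gene's orientation, the one
#' with the smallest midpoint-to-TSS distance (ties broken toward the
#' lexicographically smaller gene id). When no gene on the chromosome has
#' the THS upstream of it, the nearest gene by absolute TSS distance is
#' used as a fallback; chromosomes with no genes leave the THS unassigned
#' (counted in attribute `n_unassigned`).
#'
#' @param distal_ths Annotated distal THS tibble with `ths_id`, `chrom`,
#'   `start`, `end`.
#' @param models Gene-model tibble.
#' @return Tibble `ths_id`, `gene_id`, `distance`, `downstream` (logical:
#'   assigned by the downstream rule rather than the fallback).
#' @export
assign_distal_targets <- function(distal_ths, models) {
  n_unassigned <- 0L
  rows <- purrr::map(seq_len(nrow(distal_ths)), function(i) {
    mid <- (distal_ths$start[i] + distal_ths$end[i]) %/% 2L
    g <- models[models$chrom == distal_ths$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    updist <- if_else(g$strand == "+", g$tss - mid, mid - g$tss)
    down <- updist > 0
    if (any(down)) {
      cand <- g[down, , drop = FALSE]
      d <- updist[down]
      j <- order(d, cand$gene_id)[1]
      tibble(ths_id = distal_ths$ths_id[i], gene_id = cand$gene_id[j],
             distance = d[j], downstream = TRUE)
    } else {
      d <- abs(mid - g$tss)
      j <- order(d, g$gene_id)[1]
      tibble(ths_id = distal_ths$ths_id[i], gene_id = g$gene_id[j],
             distance = d[j], downstream = FALSE)
    }
  })
  assigned <- bind_rows(rows)
  out <- if (nrow(distal_ths)) assigned else
    tibble(ths_id = character(), gene_id = character(),
           distance = numeric(), downstream = logical())
  attr(out, "n_unassigned") <- nrow(distal_ths) - nrow(out)
  out
}

#' Fraction of target genes responsive to the treatment
#'
#' A target gene is responsive when its five-group label is anything but
#' `unchanged` (significant at transcription, translation, or both).
#' Targets without a label are counted as not responsive.
#'
#' @param target_genes Character vector of target gene ids.
#' @param group_labels Tibble `gene_id`, `group`.
#' @return Tibble `n_targets`, `n_responsive`, `pct_responsive` (2
#'   decimals).
#' @export
crosscheck_targets <- function(target_genes, group_labels) {
  if (length(target_genes) == 0L) abort("empty target gene list")
  lab <- group_labels$group[match(target_genes, group_labels$gene_id)]
  responsive <- !is.na(lab) & lab != "unchanged"
  tibble(n_targets = length(target_genes),
         n_responsive = sum(responsive),
         pct_responsive = percent_of(sum(responsive), length(target_genes)))
}

#' Hypergeometric set enrichment
#'
#' Generic over-representation engine for user-supplied term-to-gene maps
#' (e.g. GO or KEGG annotations): upper-tail hypergeometric p per term with
#' Benjamini-Hochberg correction across terms. Terms with no genes in the
#' universe are skipped.
#'
#' @param gene_set Character vector of genes of interest.
#' @param term_map Tibble with `term` and `gene_id` columns.
#' @param universe Character vector of all assayed genes.
#' @return Tibble `term`, `n_term`, `n_set`, `overlap`, `p`, `fdr`.
#' @export
set_enrichment <- function(gene_set, term_map, universe) {
  gene_set <- intersect(unique(gene_set), universe)
  N <- length(unique(universe))
  n <- length(gene_set)
  rows <- term_map |>
    filter(.data$gene_id %in% universe) |>
    group_by(.data$term) |>
    summarise(n_term = dplyr::n_distinct(.data$gene_id),
              overlap = sum(unique(.data$gene_id) %in% gene_set),
              .groups = "drop")
  if (nrow(rows) == 0L) {
    return(tibble(term = character(), n_term = integer(), n_set = integer(),
                  overlap = integer(), p = numeric(), fdr = numeric()))
  }
  rows |>
    mutate(n_set = n,
           p = phyper(.data$overlap - 1, .data$n_term, N - .data$n_term,
                      n, lower.tail = FALSE),
           fdr = bh_adjust(.data$p)) |>
    select("term", "n_term", "n_set", "overlap", "p", "fdr")
}
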