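#' Extract THS sequences from a genome
#'
#' @param ths THS tibble (`ths_id`, `chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param genome Named character vector of chromosome sequences.
#' @return Tibble `ths_id`, `seq`.
#' @export
ths_sequences <- function(ths, genome) {
  tibble(ths_id = ths$ths_id,
         seq = purrr::map_chr(seq_len(nrow(ths)), function(i) {
           substr(genome[[ths$chrom[i]]], ths$start[i] + 1L, ths$end[i])
         }))
}

#' Write the simulated raw data to disk
#'
#' Emits the files a real study would start from: genome FASTA, GFF3
#' annotation, RNA and Ribo count TSVs, sample sheets, footprint table,
#' per-replicate peak BEDs, per-site ATAC count table, the motif
#' collection in MEME format, and the ground truth as JSON.
#'
#' @param sim Output of [simulate_chill_data()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_fasta(sim$atac$genome_mod, fp("genome.fa"))
  write_gff3(sim$models, fp("annotation.gff3"))
  write_count_table(sim$expression$rna, fp("rna_counts.tsv"))
  write_count_table(sim$expression$ribo, fp("ribo_counts.tsv"))
  readr::write_tsv(sim$expression$samples, fp("samples.tsv"))
  readr::write_tsv(sim$footprints, fp("footprints.tsv"))
  readr::write_tsv(sim$atac$samples, fp("atac_samples.tsv"))
  readr::write_tsv(sim$atac$peak_counts, fp("atac_counts.tsv"))
  for (cond in unique(sim$atac$peaks$condition)) {
    for (r in unique(sim$atac$peaks$replicate)) {
      sub <- sim$atac$peaks[sim$atac$peaks$condition == cond &
                              sim$atac$peaks$replicate == r, , drop = FALSE]
      write_bed(sub[, c("chrom", "start", "end", "name")],
                fp(sprintf("peaks_%s_rep%d.bed", cond, r)))
    }
  }
  write_meme_motifs(sim$atac$motifs, fp("motifs.meme"))
  truth <- list(genes = sim$truth_genes, uorfs = sim$truth_uorfs,
                sites = sim$atac$sites[, c("site_id", "chrom", "start",
                                           "end", "membership",
                                           "cold_induced", "distal",
                                           "motif_id", "target_gene_id")])
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(out_dir)
}

#' Run the full integration pipeline on simulated data
#'
#' Simulates a complete study (genome, annotation, expression, footprints,
#' ATAC peaks), runs every analysis stage — FPKM/TE quantification,
#' two-level differential expression and the five-group classification, TE
#' differential, uORF discovery/translation calling/feature battery, THS
#' reproducibility, annotation, cold-induced calling, distal target
#' assignment and cross-check, motif enrichment and the regulatory
#' network — and writes both inputs and results under `out_dir`. All
#' randomness derives from `seed`, so a rerun with the same configuration
#' and seed is byte-identical.
#'
#' @param config A [chill_config()].
#' @param out_dir Output directory.
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list with every intermediate result.
#' @export
run_chillomics <- function(config = chill_config(), out_dir,
                           seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sim <- simulate_chill_data(config)
  write_simulation(sim, out_dir)
  fp <- function(...) file.path(out_dir, ...)

  models <- sim$models
  genome <- sim$atac$genome_mod
  samples <- sim$expression$samples
  lens <- transcript_lengths(models)

  # expression / TE / five groups -------------------------------------
  diff_rna <- diff_expression(sim$expression$rna, samples, lens,
                              level = "rna")
  diff_ribo <- diff_expression(sim$expression$ribo, samples, lens,
                               level = "ribo")
  groups <- tibble(
    gene_id = diff_rna$gene_id,
    group = classify_five_groups(diff_rna$call,
                                 diff_ribo$call[match(diff_rna$gene_id,
                                                      diff_ribo$gene_id)])
  )
  gsum <- group_summary(groups$group)

  fpkm_rna <- compute_fpkm(sim$expression$rna, lens)
  fpkm_ribo <- compute_fpkm(sim$expression$ribo, lens)
  te <- compute_te(fpkm_rna, fpkm_ribo, samples)
  te_wide <- te |>
    select("gene_id", "condition", "te") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "te",
                       names_prefix = "te_") |>
    rename(te_ck = "te_CK", te_lt = "te_LT")
  te_diff <- te_differential(te_wide)

  expression_tbl <- tibble(gene_id = diff_rna$gene_id,
                           log2fc_rna = diff_rna$log2fc,
                           fdr_rna = diff_rna$fdr,
                           call_rna = diff_rna$call,
                           log2fc_ribo = diff_ribo$log2fc,
                           fdr_ribo = diff_ribo$fdr,
                           call_ribo = diff_ribo$call) |>
    left_join(groups, by = "gene_id") |>
    left_join(te_wide, by = "gene_id")
  readr::write_tsv(expression_tbl, fp("expression.tsv"))

  # footprints ---------------------------------------------------------
  reads <- sim$footprints
  rf_fracs <- assign_reads_to_features(reads, models)
  rf_lens <- rf_length_distribution(reads)

  # uORFs ---------------------------------------------------------------
  uorfs <- find_all_uorfs(models, genome)
  uorf_results <- NULL
  if (nrow(uorfs) > 0L) {
    ivl <- bind_rows(purrr::map(seq_len(nrow(uorfs)), function(i) {
      mutate(uorfs$genomic[[i]], id = uorfs$uorf_id[i],
             chrom = uorfs$chrom[i])
    }))
    ucnt <- count_psites(reads, ivl)
    libs <- table(reads$sample)
    libs <- setNames(as.numeric(libs), names(libs))
    calls <- call_translated(ucnt, setNames(uorfs$length_nt, uorfs$uorf_id),
                             samples, libs)
    folded <- fold_energies(uorfs$seq)
    feats <- uorf_features(uorfs) |>
      mutate(nmfe = folded$nmfe)
    lt_calls <- calls |> filter(.data$condition == "LT") |>
      select("uorf_id", "translated", uorf_fpkm = "fpkm")
    feats <- left_join(feats, lt_calls, by = "uorf_id")
    class_tests <- compare_uorf_classes(feats)
    rna_cond <- te |> select("gene_id", "condition", "mean_fpkm_rna")
    u_te <- uorf_te(calls |>
                      left_join(select(uorfs, "uorf_id", "gene_id"),
                                by = "uorf_id") |>
                      select("uorf_id", "gene_id", "condition", "fpkm"),
                    rna_cond)
    te_lt_only <- te_wide |> select("gene_id", te = "te_lt")
    uclass <- te_by_uorf_class(te_lt_only,
                               feats[, c("gene_id", "translated")])
    out_tbl <- feats |>
      select("uorf_id", "gene_id", "chrom", "strand", "rel_start",
             "length_nt", "utr_length", "nmfe", "dist_to_cds_start_norm",
             "dist_to_tss_norm", "translated", "uorf_fpkm")
    readr::write_tsv(out_tbl, fp("uorfs.tsv"))
    uorf_results <- list(uorfs = feats, calls = calls,
                         class_tests = class_tests, uorf_te = u_te,
                         te_by_class = uclass)
  }

  # THSs ----------------------------------------------------------------
  peaks <- sim$atac$peaks
  ths_ck <- reproducible_ths(peaks[peaks$condition == "CK", ])
  ths_lt <- reproducible_ths(peaks[peaks$condition == "LT", ])
  venn <- condition_overlap(ths_ck, ths_lt)
  ann_lt <- annotate_ths(ths_lt, models, config$promoter_bp)
  ann_ck <- annotate_ths(ths_ck, models, config$promoter_bp)
  cold <- cold_induced_ths(ann_lt[!ann_lt$is_distal, ], ths_ck,
                           sim$atac$peak_counts, sim$atac$samples)
  cold_hit <- cold[which(cold$cold_induced), , drop = FALSE]
  distal_lt <- ann_lt[ann_lt$is_distal, , drop = FALSE]
  targets <- assign_distal_targets(distal_lt, models)
  responsive <- if (nrow(targets) > 0L) {
    crosscheck_targets(targets$gene_id, groups)
  } else NULL

  write_bed(mutate(ths_ck, name = .data$ths_id)[, c("chrom", "start",
                                                    "end", "name")],
            fp("ths_CK.bed"))
  write_bed(mutate(ths_lt, name = .data$ths_id)[, c("chrom", "start",
                                                    "end", "name")],
            fp("ths_LT.bed"))
  if (nrow(cold_hit) > 0L) {
    write_bed(mutate(cold_hit, name = .data$ths_id)[, c("chrom", "start",
                                                        "end", "name")],
              fp("cold_induced_ths.bed"))
  }
  readr::write_tsv(targets, fp("distal_targets.tsv"))

  # motifs and network ---------------------------------------------------
  motifs <- sim$atac$motifs
  enrich <- NULL
  if (nrow(distal_lt) > 0L && nrow(ths_ck) > 0L) {
    enrich <- motif_enrichment(ths_sequences(distal_lt, genome),
                               ths_sequences(ths_ck, genome), motifs)
    readr::write_tsv(enrich, fp("motif_enrichment.tsv"))
  }
  network <- NULL
  if (nrow(cold_hit) > 0L) {
    cold_ann <- ann_lt[match(cold_hit$ths_id, ann_lt$ths_id), ]
    target_map <- tibble(ths_id = cold_hit$ths_id,
                         gene_id = cold_ann$nearest_gene_id)
    hits <- scan_sequences(ths_sequences(cold_hit, genome), motifs)
    tf_ann <- tibble(motif_id = motifs$motif_id, tf = motifs$tf_family)
    network <- build_network(hits, target_map, tf_ann)
    export_network(network, fp("network_edges.tsv"), fp("network.graphml"))
  }

  summary <- list(
    n_genes = nrow(models),
    group_summary = gsum,
    te_classes = as.list(table(te_diff$te_class)),
    rf_fractions = rf_fracs,
    rf_modal_length = attr(rf_lens, "modal_length"),
    n_uorfs = nrow(uorfs),
    n_uorf_genes = dplyr::n_distinct(uorfs$gene_id),
    ths = list(ck = nrow(ths_ck), lt = nrow(ths_lt),
               shared_ck = venn$n[venn$set == "shared_ck"],
               cold_induced = nrow(cold_hit),
               distal_lt = nrow(distal_lt)),
    pct_responsive_targets = if (!is.null(responsive)) {
      responsive$pct_responsive
    } else NA,
    n_network_edges = if (!is.null(network)) nrow(network) else 0L
  )
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")

  invisible(list(sim = sim, diff_rna = diff_rna, diff_ribo = diff_ribo,
                 groups = groups, group_summary = gsum, te = te,
                 te_diff = te_diff, rf_fractions = rf_fracs,
                 rf_lengths = rf_lens, uorf = uorf_results,
                 ths_ck = ths_ck, ths_lt = ths_lt, venn = venn,
                 ann_lt = ann_lt, ann_ck = ann_ck, cold = cold,
                 cold_induced = cold_hit, targets = targets,
                 responsive = responsive, enrichment = enrich,
                 network = network, summary = summary))
}
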