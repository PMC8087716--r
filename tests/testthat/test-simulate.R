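small_cfg <- function(...) {
  defaults <- list(n_genes = 40L, n_chroms = 2L, tandem_cluster = FALSE,
                   n_footprints = 5000L, n_peaks_ck = 12L,
                   n_peaks_lt = 10L, n_decoy_peaks = 4L, seed = 101L)
  do.call(chill_config, utils::modifyList(defaults, list(...)))
}

test_that("configuration validation rejects inconsistent settings", {
  expect_error(chill_config(group_proportions = c(transcription = 0.5,
                                                  translation = 0.5,
                                                  homodirectional = 0.2,
                                                  opposite = 0, unchanged = 0)),
               "sum to 1")
  expect_error(chill_config(nb_dispersion = 0), "positive")
  expect_error(chill_config(footprint_fractions = c(utr5 = 0.5, cds = 0.4,
                                                    utr3 = 0.2,
                                                    intron = 0.2)),
               "sum to 1")
})

test_that("identical seeds give byte-identical emitted files", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_chill_data(cfg), d1)
  write_simulation(simulate_chill_data(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a different seed changes the data
  cfg2 <- small_cfg(seed = 102L)
  d3 <- withr::local_tempdir()
  write_simulation(simulate_chill_data(cfg2), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genome.fa"))),
                         unname(tools::md5sum(file.path(d3, "genome.fa")))))
})

test_that("planted uORFs are recovered exactly; none appear when disabled", {
  cfg <- chill_config(n_genes = 50L, frac_genes_with_uorfs = 0.4,
                      tandem_cluster = FALSE, seed = 1L)
  sim <- simulate_genome(cfg)
  found <- find_all_uorfs(sim$models, sim$genome)
  tu <- sim$truth_uorfs
  expect_gt(nrow(tu), 0L)
  key_found <- paste(found$gene_id, found$rel_start, found$length_nt)
  key_truth <- paste(tu$gene_id, tu$rel_start, tu$length_nt)
  expect_true(all(key_truth %in% key_found)) # recall 1.0 on the planted set

  cfg0 <- chill_config(n_genes = 30L, frac_genes_with_uorfs = 0,
                       tandem_cluster = FALSE, seed = 2L)
  sim0 <- simulate_genome(cfg0)
  expect_equal(nrow(find_all_uorfs(sim0$models, sim0$genome)), 0L)
})

test_that("emitted annotation and genome are valid per the readers", {
  cfg <- small_cfg()
  sim <- simulate_chill_data(cfg)
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  genome <- read_fasta(file.path(d, "genome.fa"))
  expect_equal(sort(names(genome)), sort(names(sim$genome)))
  models <- read_gff3(file.path(d, "annotation.gff3"))
  expect_equal(nrow(models), nrow(sim$models))
  m1 <- dplyr::arrange(models, gene_id)
  m2 <- dplyr::arrange(sim$models, gene_id)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  sheet <- read_sample_sheet(file.path(d, "samples.tsv"))
  cm <- read_count_table(file.path(d, "rna_counts.tsv"), sheet)
  expect_equal(nrow(cm), cfg$n_genes)
  mot <- read_meme_motifs(file.path(d, "motifs.meme"))
  expect_equal(nrow(mot), 3L)
})

test_that("expression simulation plants the five-group structure", {
  cfg <- chill_config(n_genes = 300L, tandem_cluster = FALSE, seed = 33L)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(sim, cfg)
  tr <- expr$truth
  expect_setequal(unique(tr$group),
                  c("transcription", "translation", "homodirectional",
                    "opposite", "unchanged"))
  expect_true(all(tr$lfc_rna[tr$group == "translation"] == 0))
  expect_true(all(tr$lfc_ribo[tr$group == "transcription"] == 0))
  expect_true(all(tr$lfc_rna[tr$group == "homodirectional"] ==
                    tr$lfc_ribo[tr$group == "homodirectional"]))
  expect_true(all(tr$lfc_rna[tr$group == "opposite"] ==
                    -tr$lfc_ribo[tr$group == "opposite"]))
  expect_true(all(abs(tr$lfc_rna) %in% c(0, cfg$effect_size_log2fc)))
  # translation-group genes at strong planted effects are predominantly
  # classified into the TE-increased/decreased classes by the TE rule
  lens <- setNames(tr$length_nt, tr$gene_id)
  fr <- compute_fpkm(expr$rna, lens)
  fb <- compute_fpkm(expr$ribo, lens)
  te <- compute_te(fr, fb, expr$samples)
  te_wide <- tidyr::pivot_wider(te[, c("gene_id", "condition", "te")],
                                names_from = "condition",
                                values_from = "te")
  names(te_wide) <- c("gene_id", "te_ck", "te_lt")
  td <- te_differential(te_wide)
  up_tr <- tr$gene_id[tr$group == "translation" & tr$lfc_ribo > 0]
  cls <- td$te_class[match(up_tr, td$gene_id)]
  expect_gt(mean(cls == "increased", na.rm = TRUE), 0.8)
})

test_that("footprint placement recovers configured fractions and lengths", {
  cfg <- small_cfg(n_footprints = 20000L, frac_genes_with_uorfs = 0)
  sim <- simulate_genome(cfg)
  reads <- simulate_footprints(sim, cfg)
  one <- reads[reads$sample == "CK_1", ]
  fr <- assign_reads_to_features(one, sim$models)
  want <- cfg$footprint_fractions
  for (cat in names(want)) {
    expect_lt(abs(fr$fraction[fr$category == cat] - want[[cat]]), 0.01)
  }
  expect_equal(attr(fr, "unassigned"), 0L)
  expect_equal(rf_modal_length(one), 32L)
  # the generator's category labels agree with the assigner
  expect_equal(unname(table(one$category)[c("utr5", "cds", "utr3",
                                            "intron")]),
               fr$n[match(c("utr5", "cds", "utr3", "intron"),
                          fr$category)], ignore_attr = TRUE)
})

test_that("untranslated uORFs receive no footprint support", {
  cfg <- chill_config(n_genes = 60L, frac_genes_with_uorfs = 0.6,
                      frac_uorfs_translated = 0.5, tandem_cluster = FALSE,
                      n_footprints = 20000L, seed = 55L)
  sim <- simulate_genome(cfg)
  reads <- simulate_footprints(sim, cfg)
  uorfs <- find_all_uorfs(sim$models, sim$genome)
  ivl <- dplyr::bind_rows(lapply(seq_len(nrow(uorfs)), function(i) {
    dplyr::mutate(uorfs$genomic[[i]], id = uorfs$uorf_id[i],
                  chrom = uorfs$chrom[i])
  }))
  cnt <- count_psites(reads, ivl)
  libs <- table(reads$sample)
  calls <- call_translated(cnt, setNames(uorfs$length_nt, uorfs$uorf_id),
                           toy_samples(), setNames(as.numeric(libs),
                                                   names(libs)))
  tu <- sim$truth_uorfs
  # the scanner renumbers candidates, so match planted to found uORFs by
  # coordinates, not by id
  key_found <- paste(uorfs$gene_id, uorfs$rel_start, uorfs$length_nt)
  key_truth <- paste(tu$gene_id, tu$rel_start, tu$length_nt)
  tu$found_id <- uorfs$uorf_id[match(key_truth, key_found)]
  expect_false(anyNA(tu$found_id))
  planted <- calls[calls$uorf_id %in% tu$found_id, ]
  truth_tr <- tu$translated[match(planted$uorf_id, tu$found_id)]
  # untranslated planted uORFs: FPKM < 1 by construction
  expect_true(all(planted$fpkm[!truth_tr] < 1))
  # translated planted uORFs: recovered with high recall
  recall <- mean(planted$translated[truth_tr])
  expect_gte(recall, 0.95)
})

test_that("ATAC simulation plants recoverable reproducible structure", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  atac <- simulate_atac(sim, cfg)
  ths_ck <- reproducible_ths(atac$peaks[atac$peaks$condition == "CK", ])
  ths_lt <- reproducible_ths(atac$peaks[atac$peaks$condition == "LT", ])
  truth_ck <- sum(atac$sites$membership != "lt_only")
  truth_lt <- sum(atac$sites$membership != "ck_only")
  expect_equal(nrow(ths_ck), truth_ck)
  expect_equal(nrow(ths_lt), truth_lt)

  # every cold-induced truth site is LT-only by construction
  expect_true(all(atac$sites$membership[atac$sites$cold_induced] ==
                    "lt_only"))
  # distal truth sites sit outside gene bodies and promoter windows
  ann <- annotate_ths(
    tibble::tibble(ths_id = atac$sites$site_id, chrom = atac$sites$chrom,
                   start = atac$sites$start, end = atac$sites$end),
    sim$models)
  expect_true(all(ann$is_distal[atac$sites$distal]))

  cfg0 <- small_cfg(frac_cold_induced = 0)
  atac0 <- simulate_atac(simulate_genome(cfg0), cfg0)
  expect_equal(sum(atac0$sites$cold_induced), 0L)
})
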