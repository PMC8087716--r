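#' Simulation configuration
#'
#' Parameters of the synthetic multi-omics generator. The defaults encode
#' the emulated study design: 3 replicates in each of two conditions (CK
#' and LT), negative-binomial counts with `Var = mu + mu^2 * dispersion`,
#' five joint transcription/translation response groups in the proportions
#' observed in the motivating data, uORFs of 60-450 nt planted in a
#' configurable fraction of 5' UTRs, ~32-nt ribosome footprints
#' distributed over transcript features, and replicate ATAC peak sets with
#' planted cold-induced sites and motif instances.
#'
#' @param n_genes Number of genes (default 400).
#' @param n_chroms Number of chromosomes genes are spread over.
#' @param utr5_len_range,cds_len_range,utr3_len_range Feature length ranges
#'   in nt (CDS lengths are rounded to whole codons).
#' @param frac_genes_with_intron Fraction of genes whose CDS is split by
#'   one intron.
#' @param intron_len_range Intron length range in nt.
#' @param intergenic_gap_range Range of intergenic gap sizes in nt.
#' @param frac_genes_with_uorfs Fraction of genes with planted uORFs.
#' @param uorfs_per_gene_range Range of planted uORFs per selected gene.
#' @param uorf_len_range Planted uORF length bounds in nt (stop included).
#' @param frac_uorfs_translated Fraction of planted uORFs that are
#'   translated (receive footprints).
#' @param tandem_cluster Plant one tandem cluster of four near-identical
#'   cold-induced genes on the last chromosome.
#' @param group_proportions Named proportions of the five response groups
#'   (must sum to 1); defaults derive from the motivating study's counts.
#' @param effect_size_log2fc Absolute log2 fold change planted in affected
#'   groups.
#' @param nb_dispersion Negative-binomial dispersion `alpha` in
#'   `Var = mu + mu^2 alpha`.
#' @param mean_count_meanlog,mean_count_sdlog Log-normal parameters of the
#'   per-gene baseline mean RNA count.
#' @param te_sdlog Log-normal spread of the baseline Ribo/RNA ratio.
#' @param uorf_te_suppression Multiplier on the Ribo mean of genes carrying
#'   at least one translated uORF (translated uORFs repress the main ORF).
#' @param n_replicates Replicates per condition.
#' @param n_footprints Ribosome footprints per Ribo-seq sample.
#' @param footprint_fractions Proportions of footprints in
#'   5' UTR/CDS/3' UTR/intron (must sum to 1); defaults mirror the
#'   motivating study's control sample.
#' @param footprint_length_probs Named probabilities of footprint lengths.
#' @param uorf_mean_reads Mean footprints per translated uORF per CK
#'   sample.
#' @param uorf_lt_boost Multiplier on translated-uORF footprint rates in
#'   LT samples (enhanced uORF translation under chilling).
#' @param n_peaks_ck,n_peaks_lt Reproducible THSs planted per condition.
#' @param frac_shared_peaks Fraction of CK sites also present in LT.
#' @param n_decoy_peaks Non-reproducible decoy peaks per condition.
#' @param frac_cold_induced Fraction of LT-only sites that are
#'   cold-induced (count fold change `cold_fc`).
#' @param cold_fc Count fold change of cold-induced sites (LT over CK).
#' @param frac_distal_peaks Fraction of sites placed in distal intergenic
#'   space (> 2 kb upstream of every TSS and outside gene bodies).
#' @param peak_width_range THS width range in bp.
#' @param peak_jitter Maximal absolute per-replicate boundary jitter in bp.
#' @param peak_mean_meanlog,peak_mean_sdlog Log-normal parameters of the
#'   per-site mean read count.
#' @param motif_insert_prob Probability that a cold-induced distal site
#'   receives a planted motif consensus.
#' @param promoter_bp Promoter window used when placing proximal sites.
#' @param seed Integer seed; every generator stage derives its RNG stream
#'   from it, so identical config + seed gives byte-identical outputs.
#' @return A `chill_config` list.
#' @export
chill_config <- function(n_genes = 400L,
                         n_chroms = 3L,
                         utr5_len_range = c(150L, 400L),
                         cds_len_range = c(900L, 2400L),
                         utr3_len_range = c(100L, 300L),
                         frac_genes_with_intron = 0.3,
                         intron_len_range = c(200L, 600L),
                         intergenic_gap_range = c(5000L, 9000L),
                         frac_genes_with_uorfs = 0.4,
                         uorfs_per_gene_range = c(1L, 3L),
                         uorf_len_range = c(60L, 450L),
                         frac_uorfs_translated = 0.5,
                         tandem_cluster = TRUE,
                         group_proportions = c(transcription = 0.1106,
                                               translation = 0.0688,
                                               homodirectional = 0.0587,
                                               opposite = 0.0070,
                                               unchanged = 0.7549),
                         effect_size_log2fc = 3,
                         nb_dispersion = 0.1,
                         mean_count_meanlog = log(200),
                         mean_count_sdlog = 1,
                         te_sdlog = 0.25,
                         uorf_te_suppression = 0.5,
                         n_replicates = 3L,
                         n_footprints = 50000L,
                         footprint_fractions = c(utr5 = 0.0234,
                                                 cds = 0.9433,
                                                 utr3 = 0.0105,
                                                 intron = 0.0228),
                         footprint_length_probs = c(`28` = 0.03, `29` = 0.05,
                                                    `30` = 0.08, `31` = 0.15,
                                                    `32` = 0.40, `33` = 0.15,
                                                    `34` = 0.09, `35` = 0.05),
                         uorf_mean_reads = 5,
                         uorf_lt_boost = 2,
                         n_peaks_ck = 60L,
                         n_peaks_lt = 50L,
                         frac_shared_peaks = 0.25,
                         n_decoy_peaks = 15L,
                         frac_cold_induced = 0.4,
                         cold_fc = 8,
                         frac_distal_peaks = 0.5,
                         peak_width_range = c(300L, 600L),
                         peak_jitter = 30L,
                         peak_mean_meanlog = log(150),
                         peak_mean_sdlog = 0.4,
                         motif_insert_prob = 0.8,
                         promoter_bp = 2000L,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$group_proportions) - 1) > 1e-6) {
    abort("group_proportions must sum to 1")
  }
  if (abs(sum(cfg$footprint_fractions) - 1) > 1e-6) {
    abort("footprint_fractions must sum to 1")
  }
  if (cfg$nb_dispersion <= 0) abort("nb_dispersion must be positive")
  if (cfg$n_genes <= 0 || cfg$n_chroms <= 0 || cfg$n_replicates < 2) {
    abort("counts in the configuration must be positive (>= 2 replicates)")
  }
  class(cfg) <- "chill_config"
  cfg
}

# stage-specific RNG stream derived from the config seed
stage_seed <- function(config, stage) {
  offsets <- c(genome = 11L, expression = 23L, footprints = 37L,
               atac = 53L)
  set.seed((config$seed + offsets[[stage]]) %% .Machine$integer.max)
}

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# codons that are neither stops nor ATG, for controlled ORF interiors
safe_codons <- function() {
  all_cod <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                   collapse = "")
  setdiff(all_cod, c(STOP_CODONS, "ATG"))
}

# background UTR sequence free of uORF candidates (rejection sampling,
# capped at 1000 attempts before shortening the UTR)
clean_utr <- function(len, min_len = 60L, max_len = 450L) {
  for (attempt in seq_len(1000L)) {
    s <- rand_dna(len)
    if (nrow(find_uorfs(s, min_len, max_len)) == 0L) return(s)
  }
  clean_utr(max(10L, as.integer(len * 0.7)), min_len, max_len)
}

# a planted ORF: ATG + interior codons free of ATG/stops + one stop
planted_orf <- function(len_nt) {
  stopifnot(len_nt %% 3L == 0L, len_nt >= 9L)
  interior <- sample(safe_codons(), len_nt / 3L - 2L, replace = TRUE)
  paste0("ATG", paste(interior, collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Generate a synthetic genome, annotation and ground truth
#'
#' Places non-overlapping genes with intergenic gaps on `n_chroms`
#' chromosomes. Selected genes carry planted uORFs (proper ORFs whose
#' interiors are free of ATG and stop codons so the planted candidate is
#' recovered exactly); background 5' UTR sequence is rejection-sampled to
#' contain no accidental uORF candidate. Optionally plants a tandem
#' cluster of four near-identical cold-induced genes on the last
#' chromosome, mimicking tandemly arranged terpene-pathway gene arrays.
#'
#' @param config A [chill_config()].
#' @return List with `genome` (named character vector), `models`
#'   (gene-model tibble), `truth_genes` (gene_id, group, sign, has_intron),
#'   `truth_uorfs` (gene_id, uorf_id, rel_start, length_nt, translated).
#' @export
simulate_genome <- function(config) {
  stage_seed(config, "genome")
  cfg <- config
  n <- cfg$n_genes

  groups <- sample(rep(names(cfg$group_proportions),
                       times = diff_round(cfg$group_proportions * n)))
  signs <- sample(c(1, -1), n, replace = TRUE)

  n_tandem <- if (isTRUE(cfg$tandem_cluster)) 4L else 0L
  with_uorf <- rep(FALSE, n)
  n_uorf_genes <- round(cfg$frac_genes_with_uorfs * (n - n_tandem))
  if (n_uorf_genes > 0) {
    with_uorf[sample(seq_len(n - n_tandem), n_uorf_genes)] <- TRUE
  }

  per_chrom <- diff_round(rep(1 / cfg$n_chroms, cfg$n_chroms) * n)
  gene_idx <- 0L
  genome <- character(0)
  models <- list()
  truth_uorfs <- list()
  tandem_template <- NULL

  for (ch in seq_len(cfg$n_chroms)) {
    chrom <- sprintf("chr%d", ch)
    pos <- 0L
    seq_parts <- character(0)
    for (k in seq_len(per_chrom[ch])) {
      gene_idx <- gene_idx + 1L
      gid <- sprintf("G%04d", gene_idx)
      is_tandem <- isTRUE(cfg$tandem_cluster) && ch == cfg$n_chroms &&
        k > per_chrom[ch] - n_tandem

      gap <- sample(cfg$intergenic_gap_range[1]:cfg$intergenic_gap_range[2],
                    1L)
      seq_parts <- c(seq_parts, rand_dna(gap))
      pos <- pos + gap

      if (is_tandem && !is.null(tandem_template)) {
        parts <- tandem_template
        # a few point substitutions keep the copies near- but not fully
        # identical
        mut <- function(s) {
          v <- strsplit(s, "")[[1]]
          i <- sample(seq_along(v), max(1L, length(v) %/% 500L))
          v[i] <- sample(DNA_BASES, length(i), replace = TRUE)
          paste(v, collapse = "")
        }
        parts$utr3 <- mut(parts$utr3)
      } else {
        utr5_len <- sample(cfg$utr5_len_range[1]:cfg$utr5_len_range[2], 1L)
        cds_len <- sample(cfg$cds_len_range[1]:cfg$cds_len_range[2], 1L)
        cds_len <- (cds_len %/% 3L) * 3L
        utr3_len <- sample(cfg$utr3_len_range[1]:cfg$utr3_len_range[2], 1L)
        utr5 <- clean_utr(utr5_len, cfg$uorf_len_range[1],
                          cfg$uorf_len_range[2])
        # plant uORFs by overwriting stretches of the clean UTR
        uorf_spec <- NULL
        if (with_uorf[gene_idx] && !is_tandem) {
          n_u <- sample(cfg$uorfs_per_gene_range[1]:
                          cfg$uorfs_per_gene_range[2], 1L)
          cursor <- 2L
          for (u in seq_len(n_u)) {
            max_len <- min(cfg$uorf_len_range[2],
                           ((nchar(utr5) - cursor - 3L) %/% 3L) * 3L)
            if (max_len < cfg$uorf_len_range[1]) break
            cand_lens <- seq(cfg$uorf_len_range[1], max_len, by = 3L)
            ulen <- cand_lens[sample.int(length(cand_lens), 1L)]
            ustart <- cursor
            orf <- planted_orf(ulen)
            substr(utr5, ustart + 1L, ustart + ulen) <- orf
            uorf_spec <- bind_rows(uorf_spec,
                                   tibble(rel_start = ustart,
                                          length_nt = ulen))
            cursor <- ustart + ulen + 3L
          }
        }
        cds <- planted_orf(cds_len)
        utr3 <- rand_dna(utr3_len)
        intron <- NULL
        if (runif(1) < cfg$frac_genes_with_intron) {
          ilen <- sample(cfg$intron_len_range[1]:cfg$intron_len_range[2], 1L)
          intron <- rand_dna(ilen)
        }
        parts <- list(utr5 = utr5, cds = cds, intron = intron, utr3 = utr3,
                      uorfs = uorf_spec)
        if (is_tandem && is.null(tandem_template)) tandem_template <- parts
        if (isTRUE(cfg$tandem_cluster) && ch == cfg$n_chroms &&
            k == per_chrom[ch] - n_tandem + 1L) {
          tandem_template <- parts
        }
      }

      strand <- sample(c("+", "-"), 1L)
      # transcript-order pieces; intron splits the CDS in half (codon
      # boundary)
      cds_len <- nchar(parts$cds)
      half <- ((cds_len %/% 2L) %/% 3L) * 3L
      tx_pieces <- if (is.null(parts$intron)) {
        list(c("utr5"), c("cds1"), c("utr3"))
      } else {
        list(c("utr5"), c("cds1"), c("intron"), c("cds2"), c("utr3"))
      }
      piece_seq <- list(
        utr5 = parts$utr5,
        cds1 = if (is.null(parts$intron)) parts$cds
               else substr(parts$cds, 1L, half),
        intron = parts$intron %||% "",
        cds2 = if (is.null(parts$intron)) ""
               else substr(parts$cds, half + 1L, cds_len),
        utr3 = parts$utr3
      )
      order_names <- unlist(tx_pieces)
      genomic_order <- if (strand == "+") order_names else rev(order_names)
      gene_seq_parts <- purrr::map_chr(genomic_order, function(p) {
        s <- piece_seq[[p]]
        if (strand == "-") revcomp(s) else s
      })
      widths <- nchar(gene_seq_parts)
      starts <- pos + cumsum(c(0L, widths[-length(widths)]))
      ends <- starts + widths
      names(starts) <- names(ends) <- genomic_order
      gene_start <- pos
      gene_end <- pos + sum(widths)
      seq_parts <- c(seq_parts, gene_seq_parts)
      pos <- gene_end

      ivl <- function(p) tibble(start = unname(starts[p]),
                                end = unname(ends[p]))
      cds_tbl <- if (is.null(parts$intron)) ivl("cds1") else
        arrange(bind_rows(ivl("cds1"), ivl("cds2")), .data$start)
      exon_pieces <- setdiff(genomic_order, "intron")
      exon_tbl <- arrange(bind_rows(purrr::map(exon_pieces, ivl)),
                          .data$start)
      # merge touching exon pieces into true exons
      exon_tbl <- merge_touching(exon_tbl)

      models[[gene_idx]] <- tibble(
        gene_id = gid, chrom = chrom, strand = strand,
        tss = if (strand == "+") gene_start else gene_end - 1L,
        start = gene_start, end = gene_end,
        exons = list(exon_tbl), cds = list(cds_tbl),
        utr5 = list(ivl("utr5")), utr3 = list(ivl("utr3"))
      )

      if (!is.null(parts$uorfs) && nrow(parts$uorfs) > 0L) {
        tr <- runif(nrow(parts$uorfs)) < cfg$frac_uorfs_translated
        truth_uorfs[[length(truth_uorfs) + 1L]] <-
          mutate(parts$uorfs, gene_id = gid, translated = tr,
                 uorf_id = paste0(gid, ".u", row_number()))
      }
      if (is_tandem || (isTRUE(cfg$tandem_cluster) && ch == cfg$n_chroms &&
                        k == per_chrom[ch] - n_tandem + 1L)) {
        groups[gene_idx] <- "homodirectional"
        signs[gene_idx] <- 1
      }
    }
    tail_gap <- sample(cfg$intergenic_gap_range[1]:
                         cfg$intergenic_gap_range[2], 1L)
    seq_parts <- c(seq_parts, rand_dna(tail_gap))
    genome[chrom] <- paste(seq_parts, collapse = "")
  }

  models <- bind_rows(models)
  truth_uorfs <- if (length(truth_uorfs)) bind_rows(truth_uorfs) else
    tibble(rel_start = integer(), length_nt = integer(),
           gene_id = character(), translated = logical(),
           uorf_id = character())
  truth_genes <- tibble(
    gene_id = models$gene_id,
    group = groups,
    sign = signs,
    has_translated_uorf = models$gene_id %in%
      truth_uorfs$gene_id[truth_uorfs$translated]
  )
  list(genome = genome, models = models, truth_genes = truth_genes,
       truth_uorfs = truth_uorfs)
}

# largest-remainder rounding of proportions to integer counts
diff_round <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  need <- round(sum(x)) - sum(fl)
  if (need > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(need)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

merge_touching <- function(tbl) {
  if (nrow(tbl) <= 1L) return(tbl)
  out <- tbl[1, ]
  for (i in 2:nrow(tbl)) {
    if (tbl$start[i] <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], tbl$end[i])
    } else {
      out <- bind_rows(out, tbl[i, ])
    }
  }
  out
}

transcript_lengths <- function(models) {
  vapply(models$exons, function(t) sum(t$end - t$start), numeric(1)) |>
    setNames(models$gene_id)
}

#' Simulate RNA-seq and Ribo-seq count matrices
#'
#' Counts are negative binomial with `Var = mu + mu^2 * dispersion`.
#' LT means shift by the planted log2 fold change per group:
#' transcription-group genes shift RNA only (Ribo coupling 0),
#' translation-group genes shift Ribo only, homodirectional genes shift
#' both in the same direction, opposite genes in opposite directions,
#' unchanged genes neither. Genes carrying a translated uORF have their
#' Ribo mean multiplied by `uorf_te_suppression`.
#'
#' @param sim Output of [simulate_genome()].
#' @param config The [chill_config()] used to generate `sim`.
#' @return List with `rna` and `ribo` count tibbles (`feature_id` +
#'   samples), `samples` sheet, and `truth` (per-gene true log2FC at both
#'   levels).
#' @export
simulate_expression <- function(sim, config) {
  stage_seed(config, "expression")
  cfg <- config
  genes <- sim$truth_genes
  n <- nrow(genes)
  lens <- transcript_lengths(sim$models)[genes$gene_id]

  base_rna <- rlnorm(n, cfg$mean_count_meanlog, cfg$mean_count_sdlog)
  te_base <- rlnorm(n, 0, cfg$te_sdlog)
  te_base[genes$has_translated_uorf] <-
    te_base[genes$has_translated_uorf] * cfg$uorf_te_suppression
  base_ribo <- base_rna * te_base

  lfc <- cfg$effect_size_log2fc * genes$sign
  lfc_rna <- if_else(genes$group %in% c("transcription", "homodirectional",
                                        "opposite"), lfc, 0)
  lfc_ribo <- dplyr::case_when(
    genes$group %in% c("translation", "homodirectional") ~ lfc,
    genes$group == "opposite" ~ -lfc,
    TRUE ~ 0
  )

  samples <- tibble(
    sample = c(paste0("CK_", seq_len(cfg$n_replicates)),
               paste0("LT_", seq_len(cfg$n_replicates))),
    condition = rep(c("CK", "LT"), each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), 2L)
  )

  draw <- function(mu_ck, mu_lt) {
    out <- tibble(feature_id = genes$gene_id)
    for (i in seq_len(nrow(samples))) {
      mu <- if (samples$condition[i] == "CK") mu_ck else mu_lt
      out[[samples$sample[i]]] <- rnbinom(n, mu = mu,
                                          size = 1 / cfg$nb_dispersion)
    }
    out
  }
  rna <- draw(base_rna, base_rna * 2^lfc_rna)
  ribo <- draw(base_ribo, base_ribo * 2^lfc_ribo)

  truth <- tibble(gene_id = genes$gene_id, group = genes$group,
                  lfc_rna = lfc_rna, lfc_ribo = lfc_ribo,
                  length_nt = unname(lens))
  list(rna = rna, ribo = ribo, samples = samples, truth = truth)
}

# genomic intervals of one feature category for one gene-model row
category_intervals <- function(gene, category) {
  switch(category,
    utr5 = gene$utr5[[1]],
    utr3 = gene$utr3[[1]],
    cds = gene$cds[[1]],
    intron = {
      ex <- gene$exons[[1]]
      sp <- tibble(start = gene$start, end = gene$end)
      gaps <- tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
      gaps[gaps$end > gaps$start, , drop = FALSE]
    }
  )
}

sample_positions_in <- function(ivl, n) {
  w <- ivl$end - ivl$start
  pick <- sample.int(nrow(ivl), n, replace = TRUE, prob = w)
  ivl$start[pick] + floor(runif(n) * w[pick])
}

#' Simulate ribosome footprint placements
#'
#' Emits per-read 5' end positions and lengths for each Ribo-seq sample.
#' Read lengths follow a discrete distribution peaked at 32 nt. The P-site
#' (5' end + 12 nt in transcript orientation) of each read lands in a
#' feature category drawn from `footprint_fractions`; within the 5' UTR
#' budget, translated uORFs receive Poisson read counts at
#' `uorf_mean_reads` per CK sample (times `uorf_lt_boost` in LT) and the
#' remaining 5' UTR reads avoid untranslated uORF intervals, so
#' untranslated uORFs stay below the translation threshold by
#' construction.
#'
#' @param sim Output of [simulate_genome()].
#' @param config The generating [chill_config()].
#' @return Tibble `sample`, `condition`, `chrom`, `strand`, `five_prime`,
#'   `length`, `category`.
#' @export
simulate_footprints <- function(sim, config) {
  stage_seed(config, "footprints")
  cfg <- config
  models <- sim$models
  psite_offset <- 12L
  lens_probs <- cfg$footprint_length_probs
  lens_vals <- as.integer(names(lens_probs))

  # per-gene weights from the expression truth would couple stages; use
  # fresh lognormal weights so this stage is self-contained
  w_gene <- rlnorm(nrow(models), 0, 1)

  uorfs <- sim$truth_uorfs
  uorf_genomic <- NULL
  if (nrow(uorfs) > 0L) {
    uorf_genomic <- bind_rows(purrr::map(seq_len(nrow(uorfs)), function(i) {
      g <- models[models$gene_id == uorfs$gene_id[i], ]
      ivl <- utr_rel_to_genomic(g, uorfs$rel_start[i],
                                uorfs$rel_start[i] + uorfs$length_nt[i])
      mutate(ivl, uorf_id = uorfs$uorf_id[i], chrom = g$chrom,
             strand = g$strand, translated = uorfs$translated[i])
    }))
  }

  samples <- tibble(
    sample = c(paste0("CK_", seq_len(cfg$n_replicates)),
               paste0("LT_", seq_len(cfg$n_replicates))),
    condition = rep(c("CK", "LT"), each = cfg$n_replicates)
  )

  intron_ok <- vapply(seq_len(nrow(models)), function(i) {
    nrow(category_intervals(models[i, ], "intron")) > 0L
  }, logical(1))

  all_reads <- purrr::map(seq_len(nrow(samples)), function(si) {
    cond <- samples$condition[si]
    n_total <- cfg$n_footprints
    cat_draw <- sample(names(cfg$footprint_fractions), n_total,
                       replace = TRUE, prob = cfg$footprint_fractions)
    n_by_cat <- table(factor(cat_draw,
                             levels = names(cfg$footprint_fractions)))

    reads <- list()
    # uORF reads come out of the utr5 budget
    n_utr5 <- n_by_cat[["utr5"]]
    n_uorf_reads <- 0L
    if (!is.null(uorf_genomic) && any(uorf_genomic$translated)) {
      tr <- uorf_genomic[uorf_genomic$translated, , drop = FALSE]
      rate <- cfg$uorf_mean_reads *
        if (cond == "LT") cfg$uorf_lt_boost else 1
      per_u <- rpois(length(unique(tr$uorf_id)), rate)
      names(per_u) <- unique(tr$uorf_id)
      for (uid in names(per_u)) {
        nu <- min(per_u[[uid]], n_utr5 - n_uorf_reads)
        if (nu <= 0L) next
        ivl <- tr[tr$uorf_id == uid, , drop = FALSE]
        ps <- sample_positions_in(ivl[, c("start", "end")], nu)
        reads[[length(reads) + 1L]] <- tibble(
          chrom = ivl$chrom[1], strand = ivl$strand[1], psite = ps,
          category = "utr5")
        n_uorf_reads <- n_uorf_reads + nu
      }
    }

    for (cat in names(cfg$footprint_fractions)) {
      n_cat <- n_by_cat[[cat]]
      if (cat == "utr5") n_cat <- n_cat - n_uorf_reads
      if (n_cat <= 0L) next
      ok <- if (cat == "intron") which(intron_ok) else seq_len(nrow(models))
      if (length(ok) == 0L) next
      g_pick <- ok[sample.int(length(ok), n_cat, replace = TRUE,
                              prob = w_gene[ok])]
      picks <- split(seq_len(n_cat), g_pick)
      for (gi_chr in names(picks)) {
        gi <- as.integer(gi_chr)
        g <- models[gi, ]
        ivl <- category_intervals(g, cat)
        if (cat == "utr5" && !is.null(uorf_genomic)) {
          # keep background UTR reads out of every uORF interval so
          # untranslated uORFs receive no footprints
          gu <- uorf_genomic[uorf_genomic$chrom == g$chrom &
                               uorf_genomic$start >= g$start &
                               uorf_genomic$end <= g$end, , drop = FALSE]
          if (nrow(gu) > 0L) {
            keep <- IRanges::setdiff(
              intervals_to_iranges(ivl$start, ivl$end),
              intervals_to_iranges(gu$start, gu$end))
            ivl <- tibble(start = IRanges::start(keep) - 1L,
                          end = IRanges::end(keep))
            if (nrow(ivl) == 0L) next
          }
        }
        ps <- sample_positions_in(ivl, length(picks[[gi_chr]]))
        reads[[length(reads) + 1L]] <- tibble(
          chrom = g$chrom, strand = g$strand, psite = ps, category = cat)
      }
    }
    out <- bind_rows(reads)
    out$length <- sample(lens_vals, nrow(out), replace = TRUE,
                         prob = lens_probs)
    out$five_prime <- if_else(out$strand == "+",
                              out$psite - psite_offset,
                              out$psite + psite_offset)
    out$sample <- samples$sample[si]
    out$condition <- cond
    select(out, "sample", "condition", "chrom", "strand", "five_prime",
           "length", "category")
  })
  bind_rows(all_reads)
}

#' Simulate replicate ATAC peak sets with planted structure
#'
#' Plants reproducible THSs (present, jittered, in every replicate of
#' their condition), non-reproducible decoys (present in a strict subset
#' of replicates), cold-induced LT-only sites with a planted count fold
#' change, distal sites (> `promoter_bp` upstream of every TSS and outside
#' gene bodies) versus proximal sites placed in promoter windows, and
#' motif consensus instances inserted into cold-induced distal site
#' sequences. Per-site read counts for all samples are negative binomial.
#'
#' @param sim Output of [simulate_genome()].
#' @param config The generating [chill_config()].
#' @return List with `peaks` (tibble `chrom`, `start`, `end`, `name`,
#'   `condition`, `replicate`), `sites` (ground-truth tibble with
#'   `cold_induced`, `distal`, `motif_id`, `target_gene_id`),
#'   `peak_counts` (site intervals + one count column per ATAC sample),
#'   `samples` sheet, `motifs` motif tibble, `genome_mod` the genome with
#'   motif instances inserted.
#' @export
simulate_atac <- function(sim, config) {
  stage_seed(config, "atac")
  cfg <- config
  models <- sim$models
  genome <- sim$genome

  prom <- promoter_windows(models, cfg$promoter_bp)
  blocked <- GenomicRanges::reduce(c(
    make_granges(models$chrom, models$start, models$end),
    make_granges(prom$chrom, pmin(prom$start, prom$end),
                 pmax(prom$start, prom$end) + 1L)
  ))
  chrom_lens <- nchar(genome)
  genome_gr <- make_granges(names(chrom_lens), rep(0L, length(chrom_lens)),
                            unname(chrom_lens))
  open_space <- GenomicRanges::setdiff(genome_gr, blocked)
  distal_space <- open_space[GenomicRanges::width(open_space) >
                               max(cfg$peak_width_range) + 200L]
  prom_ok <- prom[prom$end - prom$start >= max(cfg$peak_width_range), ,
                  drop = FALSE]

  place_site <- function(distal) {
    w <- sample(cfg$peak_width_range[1]:cfg$peak_width_range[2], 1L)
    if (distal) {
      i <- sample.int(length(distal_space), 1L,
                      prob = GenomicRanges::width(distal_space))
      lo <- GenomicRanges::start(distal_space[i]) - 1L + 100L
      hi <- GenomicRanges::end(distal_space[i]) - 100L - w
      s <- lo + floor(runif(1) * max(1L, hi - lo))
      tibble(chrom = as.character(GenomicRanges::seqnames(distal_space[i])),
             start = as.integer(s), end = as.integer(s + w))
    } else {
      i <- sample.int(nrow(prom_ok), 1L)
      lo <- prom_ok$start[i]
      hi <- prom_ok$end[i] - w
      s <- lo + floor(runif(1) * max(1L, hi - lo))
      tibble(chrom = prom_ok$chrom[i], start = as.integer(s),
             end = as.integer(s + w))
    }
  }

  n_shared <- round(cfg$frac_shared_peaks * min(cfg$n_peaks_ck,
                                                cfg$n_peaks_lt))
  n_ck_only <- cfg$n_peaks_ck - n_shared
  n_lt_only <- cfg$n_peaks_lt - n_shared
  n_cold <- round(cfg$frac_cold_induced * n_lt_only)

  mk_sites <- function(n, membership) {
    if (n == 0L) return(NULL)
    bind_rows(purrr::map(seq_len(n), function(i) {
      place_site(runif(1) < cfg$frac_distal_peaks)
    })) |> mutate(membership = membership)
  }
  sites <- bind_rows(
    mk_sites(n_shared, "shared"),
    mk_sites(n_ck_only, "ck_only"),
    mk_sites(n_lt_only, "lt_only")
  )
  # drop accidental overlaps between planted sites (keep the first site of
  # every merged cluster)
  gr <- make_granges(sites$chrom, sites$start, sites$end)
  ov_cluster <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(gr)))
  sites <- sites[!duplicated(ov_cluster), , drop = FALSE]

  sites$site_id <- sprintf("site_%03d", seq_len(nrow(sites)))
  lt_only_idx <- which(sites$membership == "lt_only")
  sites$cold_induced <- FALSE
  if (n_cold > 0L && length(lt_only_idx) > 0L) {
    sites$cold_induced[lt_only_idx[seq_len(min(n_cold,
                                               length(lt_only_idx)))]] <- TRUE
  }
  ann <- annotate_ths(
    tibble(ths_id = sites$site_id, chrom = sites$chrom,
           start = sites$start, end = sites$end),
    models, promoter_bp = cfg$promoter_bp)
  sites$distal <- ann$is_distal

  # motif collection: strong 8-mer consensus PWMs for three TF families
  motifs <- default_motifs()
  sites$motif_id <- NA_character_
  ins_idx <- which(sites$cold_induced)
  for (i in ins_idx) {
    if (runif(1) >= cfg$motif_insert_prob) next
    m <- sample.int(nrow(motifs), 1L)
    cons <- pwm_consensus(motifs$pwm[[m]])
    w <- nchar(cons)
    off <- sites$start[i] + 50L + floor(runif(1) *
                                          (sites$end[i] - sites$start[i] -
                                             100L - w))
    substr(genome[[sites$chrom[i]]], off + 1L, off + w) <- cons
    sites$motif_id[i] <- motifs$motif_id[m]
  }

  # true targets: closest downstream gene for distal sites, nearest gene
  # (by TSS) for proximal ones
  tg <- assign_distal_targets(
    tibble(ths_id = sites$site_id, chrom = sites$chrom,
           start = sites$start, end = sites$end)[sites$distal, ,
                                                 drop = FALSE],
    models)
  sites$target_gene_id <- if_else(
    sites$distal,
    tg$gene_id[match(sites$site_id, tg$ths_id)],
    ann$nearest_gene_id)

  # replicate peak BEDs
  reps <- seq_len(cfg$n_replicates)
  jitter1 <- function(x) x + sample(-cfg$peak_jitter:cfg$peak_jitter, 1L)
  peaks <- list()
  emit_peak <- function(i, cond, r) {
    tibble(chrom = sites$chrom[i],
           start = jitter1(sites$start[i]),
           end = jitter1(sites$end[i]),
           name = sites$site_id[i],
           condition = cond, replicate = r)
  }
  for (i in seq_len(nrow(sites))) {
    conds <- switch(sites$membership[i], shared = c("CK", "LT"),
                    ck_only = "CK", lt_only = "LT")
    for (cond in conds) for (r in reps) {
      peaks[[length(peaks) + 1L]] <- emit_peak(i, cond, r)
    }
  }
  # decoys: present in a strict subset of replicates; kept clear of the
  # planted sites so they never extend a reproducible chain
  site_gr <- make_granges(sites$chrom, sites$start - 100L, sites$end + 100L)
  for (cond in c("CK", "LT")) {
    for (d in seq_len(cfg$n_decoy_peaks)) {
      s <- place_site(runif(1) < cfg$frac_distal_peaks)
      for (try in seq_len(50L)) {
        if (!any(IRanges::overlapsAny(make_granges(s$chrom, s$start, s$end),
                                      site_gr))) break
        s <- place_site(runif(1) < cfg$frac_distal_peaks)
      }
      site_gr <- c(site_gr, make_granges(s$chrom, s$start - 100L,
                                         s$end + 100L))
      in_reps <- sample(reps, sample(seq_len(cfg$n_replicates - 1L), 1L))
      for (r in in_reps) {
        peaks[[length(peaks) + 1L]] <- tibble(
          chrom = s$chrom, start = jitter1(s$start), end = jitter1(s$end),
          name = sprintf("decoy_%s_%02d", cond, d),
          condition = cond, replicate = r)
      }
    }
  }
  peaks <- bind_rows(peaks)

  samples <- tibble(
    sample = c(paste0("ATAC_CK_", reps), paste0("ATAC_LT_", reps)),
    condition = rep(c("CK", "LT"), each = cfg$n_replicates),
    replicate = rep(reps, 2L)
  )
  base_mu <- rlnorm(nrow(sites), cfg$peak_mean_meanlog, cfg$peak_mean_sdlog)
  peak_counts <- tibble(chrom = sites$chrom, start = sites$start,
                        end = sites$end, site_id = sites$site_id)
  for (i in seq_len(nrow(samples))) {
    mu <- base_mu
    if (samples$condition[i] == "LT") {
      mu <- if_else(sites$cold_induced, base_mu * cfg$cold_fc, base_mu)
    }
    peak_counts[[samples$sample[i]]] <-
      rnbinom(nrow(sites), mu = mu, size = 1 / cfg$nb_dispersion)
  }

  list(peaks = peaks, sites = as_tibble(sites), peak_counts = peak_counts,
       samples = samples, motifs = motifs, genome_mod = genome)
}

pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm, 1, which.max)], collapse = "")
}

consensus_pwm <- function(consensus, strength = 0.97) {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - strength) / 3, nrow = length(bases), ncol = 4,
              dimnames = list(NULL, DNA_BASES))
  for (i in seq_along(bases)) m[i, bases[i]] <- strength
  m
}

# 8-mer consensus motifs for three cold-response TF families
default_motifs <- function() {
  tibble(
    motif_id = c("ERF_GCC", "WRKY_Wbox", "TCP_site"),
    tf_family = c("AP2/ERF", "WRKY", "TCP"),
    width = 8L,
    pwm = list(consensus_pwm("AGCCGCCA"),
               consensus_pwm("TTTGACCT"),
               consensus_pwm("GTGGTCCC"))
  )
}

#' Run every simulation stage
#'
#' @param config A [chill_config()].
#' @return List with the genome/annotation, expression matrices, footprint
#'   table and ATAC data, plus all ground truth.
#' @export
simulate_chill_data <- function(config = chill_config()) {
  sim <- simulate_genome(config)
  expr <- simulate_expression(sim, config)
  reads <- simulate_footprints(sim, config)
  atac <- simulate_atac(sim, config)
  c(sim, list(expression = expr, footprints = reads, atac = atac,
              config = config))
}
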