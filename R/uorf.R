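#' Find candidate upstream ORFs in a 5' UTR sequence
#'
#' Scans every ATG in all three frames; each candidate extends from its ATG
#' to the first in-frame stop codon within the UTR (stop included in the
#' length). Candidates are kept when their length is within
#' `[min_len, max_len]` nt; ORFs lacking an in-frame stop before the UTR 3'
#' end are discarded. Nested ATGs sharing a stop yield separate candidates.
#'
#' @param utr5_sequence Spliced 5' UTR sequence in transcript orientation.
#' @param min_len,max_len Inclusive length bounds in nt (defaults 60 and
#'   450, stop codon included).
#' @return Tibble with `rel_start` (0-based position of the A of ATG),
#'   `rel_end` (0-based half-open end just past the stop), `length_nt`,
#'   `frame` (`rel_start %% 3`) and `seq`.
#' @export
find_uorfs <- function(utr5_sequence, min_len = 60L, max_len = 450L) {
  stopifnot(is.character(utr5_sequence), length(utr5_sequence) == 1L)
  s <- toupper(utr5_sequence)
  if (!grepl("^[ACGTN]*$", s)) {
    abort("UTR sequence contains characters outside A/C/G/T/N")
  }
  n <- nchar(s)
  empty <- tibble(rel_start = integer(), rel_end = integer(),
                  length_nt = integer(), frame = integer(), seq = character())
  if (n < min_len) return(empty)

  atg <- as.integer(gregexpr("ATG", s, fixed = TRUE)[[1]])
  atg <- atg[atg > 0] - 1L # 0-based
  if (length(atg) == 0L) return(empty)

  # 0-based positions of all stop-codon starts
  stops <- sort(unique(unlist(lapply(STOP_CODONS, function(cod) {
    p <- as.integer(gregexpr(cod, s, fixed = TRUE)[[1]])
    p[p > 0] - 1L
  }))))

  out <- purrr::map(atg, function(a) {
    cand <- stops[stops >= a + 3L & (stops - a) %% 3L == 0L]
    if (length(cand) == 0L) return(NULL)
    stop_start <- cand[1]
    end <- stop_start + 3L
    if (end > n) return(NULL)
    len <- end - a
    if (len < min_len || len > max_len) return(NULL)
    tibble(rel_start = a, rel_end = end, length_nt = len,
           frame = a %% 3L, seq = substr(s, a + 1L, end))
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) empty else arrange(res, .data$rel_start)
}

# Spliced 5' UTR sequence in transcript orientation for one gene-model row.
utr5_sequence <- function(gene, genome) {
  ivl <- gene$utr5[[1]]
  if (nrow(ivl) == 0L) return("")
  chrom_seq <- genome[[gene$chrom]]
  parts <- substring(chrom_seq, ivl$start + 1L, ivl$end)
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

# Map a transcript-relative half-open window within the (possibly spliced)
# 5' UTR back to genomic 0-based half-open intervals.
utr_rel_to_genomic <- function(gene, rel_start, rel_end) {
  ivl <- gene$utr5[[1]]
  widths <- ivl$end - ivl$start
  if (gene$strand == "-") {
    ord <- rev(seq_len(nrow(ivl)))
  } else {
    ord <- seq_len(nrow(ivl))
  }
  offs <- cumsum(c(0L, widths[ord]))[seq_along(ord)]
  pieces <- purrr::map(seq_along(ord), function(k) {
    i <- ord[k]
    lo <- max(rel_start, offs[k])
    hi <- min(rel_end, offs[k] + widths[i])
    if (lo >= hi) return(NULL)
    if (gene$strand == "+") {
      tibble(start = ivl$start[i] + (lo - offs[k]),
             end = ivl$start[i] + (hi - offs[k]))
    } else {
      tibble(start = ivl$end[i] - (hi - offs[k]),
             end = ivl$end[i] - (lo - offs[k]))
    }
  })
  arrange(bind_rows(pieces), .data$start)
}

#' Find uORF candidates for every gene model
#'
#' Extracts each gene's spliced 5' UTR from the genome and applies
#' [find_uorfs()], attaching genomic coordinates of each candidate.
#'
#' @param models Gene-model tibble (see [read_gff3()]).
#' @param genome Named character vector of chromosome sequences.
#' @inheritParams find_uorfs
#' @return Tibble with `uorf_id`, `gene_id`, `chrom`, `strand`,
#'   `rel_start`, `rel_end`, `length_nt`, `frame`, `seq`, `utr_length`, and
#'   a list-column `genomic` of 0-based half-open genomic intervals.
#' @export
find_all_uorfs <- function(models, genome, min_len = 60L, max_len = 450L) {
  rows <- purrr::map(seq_len(nrow(models)), function(i) {
    g <- models[i, ]
    utr <- utr5_sequence(g, genome)
    if (nchar(utr) == 0L) return(NULL)
    cand <- find_uorfs(utr, min_len = min_len, max_len = max_len)
    if (nrow(cand) == 0L) return(NULL)
    cand$gene_id <- g$gene_id
    cand$chrom <- g$chrom
    cand$strand <- g$strand
    cand$utr_length <- nchar(utr)
    cand$genomic <- purrr::map2(cand$rel_start, cand$rel_end,
                                function(a, b) utr_rel_to_genomic(g, a, b))
    cand
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  out <- out |>
    group_by(.data$gene_id) |>
    mutate(uorf_id = paste0(.data$gene_id, ".u", row_number())) |>
    ungroup()
  select(out, "uorf_id", "gene_id", "chrom", "strand", "rel_start",
         "rel_end", "length_nt", "frame", "seq", "utr_length", "genomic")
}

#' Call translated uORFs from footprint FPKM
#'
#' A uORF is translated in a condition when its footprint FPKM (counts of
#' footprints with P-site inside the uORF, uORF length as feature length,
#' footprint library size as denominator), averaged over the condition's
#' replicates, is at least `min_fpkm`. The boundary is inclusive.
#'
#' @param uorf_counts Tibble `feature_id` + one count column per sample
#'   (P-site counts per uORF).
#' @param lengths Named vector of uORF lengths in nt.
#' @param samples Sample sheet tibble (`sample`, `condition`, `replicate`).
#' @param library_sizes Named vector of total footprint counts per sample.
#' @param min_fpkm Translation threshold (default 1).
#' @return Tibble `uorf_id`, `condition`, `fpkm`, `translated`.
#' @export
call_translated <- function(uorf_counts, lengths, samples, library_sizes,
                            min_fpkm = 1) {
  fpkm <- compute_fpkm(uorf_counts, lengths, library_sizes = library_sizes)
  long <- tidyr::pivot_longer(fpkm, -"feature_id", names_to = "sample",
                              values_to = "fpkm")
  long |>
    inner_join(samples, by = "sample") |>
    group_by(uorf_id = .data$feature_id, condition = .data$condition) |>
    summarise(fpkm = mean(.data$fpkm), .groups = "drop") |>
    mutate(translated = .data$fpkm >= min_fpkm)
}

#' Positional features of a uORF within its 5' UTR
#'
#' Adds the normalized distances used to characterize uORFs: distance from
#' the uORF end to the main-ORF (CDS) start and distance from the uORF
#' start to the TSS, both normalized by the 5' UTR length so they lie in
#' `[0, 1]`.
#'
#' @param uorfs Tibble with `rel_start`, `rel_end` and `utr_length` columns
#'   (e.g. from [find_all_uorfs()]).
#' @return Input with `dist_to_cds_start_norm` and `dist_to_tss_norm` added.
#' @export
uorf_features <- function(uorfs) {
  if (any(uorfs$utr_length <= 0)) abort("UTR length must be positive")
  mutate(uorfs,
         dist_to_cds_start_norm =
           (.data$utr_length - .data$rel_end) / .data$utr_length,
         dist_to_tss_norm = .data$rel_start / .data$utr_length)
}

#' Sequence composition around uORF start codons, by translation class
#'
#' For each class (translated / untranslated), builds a position frequency
#' matrix and a per-position GC fraction over windows of `flank` nt either
#' side of the ATG. Windows truncated by the UTR boundary are dropped.
#'
#' @param uorfs Tibble with `utr_seq`, `rel_start` and logical `translated`
#'   columns.
#' @param flank Flank size in nt (default 10).
#' @return Tibble with `class`, `position` (labels `-flank..-1, A, T, G,
#'   +1..+flank`), frequencies `A`, `C`, `G`, `T` (each column sums to 1
#'   within a class) and `gc`.
#' @export
start_context_profiles <- function(uorfs, flank = 10L) {
  stopifnot(all(c("utr_seq", "rel_start", "translated") %in% names(uorfs)))
  width <- 2L * flank + 3L
  labels <- c(paste0("-", flank:1), "A", "T", "G", paste0("+", 1:flank))
  one_class <- function(sub, cls) {
    if (nrow(sub) == 0L) abort(sprintf("empty uORF class '%s'", cls))
    wins <- purrr::map2_chr(sub$utr_seq, sub$rel_start, function(s, a) {
      lo <- a - flank
      hi <- a + 3L + flank
      if (lo < 0L || hi > nchar(s)) NA_character_
      else substr(s, lo + 1L, hi)
    })
    wins <- wins[!is.na(wins)]
    if (length(wins) == 0L) abort(sprintf("no full windows in class '%s'", cls))
    mat <- do.call(rbind, strsplit(wins, ""))
    freq <- sapply(seq_len(width), function(j) {
      tab <- table(factor(mat[, j], levels = DNA_BASES))
      as.numeric(tab) / sum(tab)
    })
    tibble(class = cls, position = labels,
           A = freq[1, ], C = freq[2, ], G = freq[3, ], T = freq[4, ],
           gc = freq[2, ] + freq[3, ])
  }
  bind_rows(
    one_class(uorfs[uorfs$translated, , drop = FALSE], "translated"),
    one_class(uorfs[!uorfs$translated, , drop = FALSE], "untranslated")
  )
}

#' Compare scalar features between translated and untranslated uORFs
#'
#' Welch two-sample t-test per feature; features whose smaller class has
#' fewer than 2 values are skipped with a warning.
#'
#' @param uorfs Tibble with logical `translated` plus the feature columns.
#' @param features Character vector of feature column names.
#' @return Tibble `feature`, `mean_translated`, `mean_untranslated`, `t`, `p`.
#' @export
compare_uorf_classes <- function(uorfs,
                                 features = c("length_nt", "utr_length",
                                              "nmfe", "dist_to_cds_start_norm",
                                              "dist_to_tss_norm")) {
  stopifnot("translated" %in% names(uorfs))
  features <- intersect(features, names(uorfs))
  rows <- purrr::map(features, function(f) {
    x <- uorfs[[f]][uorfs$translated]
    y <- uorfs[[f]][!uorfs$translated]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      warn(sprintf("skipping feature '%s': class with < 2 values", f))
      return(NULL)
    }
    tt <- welch_t_test(x, y)
    tibble(feature = f, mean_translated = mean(x),
           mean_untranslated = mean(y), t = tt$t, p = tt$p)
  })
  bind_rows(rows)
}

#' Compare gene TE across uORF-translation classes
#'
#' Splits genes into those with no, one, or multiple translated uORFs and
#' compares the TE distributions of the classes pairwise with the
#' two-sample Kolmogorov-Smirnov test.
#'
#' @param gene_te Tibble with `gene_id` and `te`.
#' @param uorf_calls Tibble with `gene_id` and logical `translated` (one row
#'   per uORF; a single condition's calls).
#' @return List with `classes` (tibble `gene_id`, `n_translated`, `class`,
#'   `te`) and `tests` (tibble `comparison`, `D`, `p`).
#' @export
te_by_uorf_class <- function(gene_te, uorf_calls) {
  per_gene <- uorf_calls |>
    group_by(.data$gene_id) |>
    summarise(n_translated = sum(.data$translated), .groups = "drop") |>
    mutate(class = dplyr::case_when(
      .data$n_translated == 0L ~ "none",
      .data$n_translated == 1L ~ "one",
      TRUE ~ "multiple"
    ))
  classes <- inner_join(per_gene, gene_te, by = "gene_id") |>
    filter(!is.na(.data$te))
  pairs <- list(c("none", "one"), c("none", "multiple"), c("one", "multiple"))
  tests <- purrr::map(pairs, function(pr) {
    x <- classes$te[classes$class == pr[1]]
    y <- classes$te[classes$class == pr[2]]
    if (length(x) == 0L || length(y) == 0L) return(NULL)
    ks <- ks_two_sample(x, y)
    tibble(comparison = paste(pr, collapse = " vs "), D = ks$D, p = ks$p)
  })
  list(classes = classes, tests = bind_rows(tests))
}

#' TE of uORFs per condition
#'
#' uORF translational efficiency is the uORF's footprint FPKM divided by
#' its host gene's RNA FPKM in the same condition.
#'
#' @param uorf_fpkm Tibble `uorf_id`, `gene_id`, `condition`, `fpkm`
#'   (footprint FPKM, e.g. from [call_translated()] joined to uORF ids).
#' @param gene_rna_fpkm Tibble `gene_id`, `condition`, `mean_fpkm_rna`.
#' @param min_rna_fpkm RNA expression filter below which TE is undefined.
#' @return Tibble `uorf_id`, `gene_id`, `condition`, `te`.
#' @export
uorf_te <- function(uorf_fpkm, gene_rna_fpkm, min_rna_fpkm = 1) {
  inner_join(uorf_fpkm, gene_rna_fpkm, by = c("gene_id", "condition")) |>
    mutate(te = if_else(.data$mean_fpkm_rna >= min_rna_fpkm,
                        .data$fpkm / .data$mean_fpkm_rna, NA_real_)) |>
    select("uorf_id", "gene_id", "condition", "te")
}
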