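# Log-odds scoring matrix with pseudo-probability flooring, plus its
# integerized form and the exact score distribution over i.i.d. background
# sequence (dynamic program on a discretized score lattice).
pwm_score_model <- function(pwm, background = rep(0.25, 4),
                            floor_prob = 1e-3, bin = 0.005) {
  stopifnot(ncol(pwm) == 4L, all(pwm >= 0))
  background <- background / sum(background)
  p <- pmax(pwm, floor_prob)
  p <- p / rowSums(p)
  S <- log2(sweep(p, 2, background, "/")) # bits
  K <- round(S / bin)
  L <- nrow(K)
  # convolve position by position
  cur <- c(1) # P(score_int = offset_cur)
  off <- 0L
  for (i in seq_len(L)) {
    ks <- K[i, ]
    new_lo <- off + min(ks)
    new_hi <- off + length(cur) - 1L + max(ks)
    new <- rep(0, new_hi - new_lo + 1L)
    for (b in 1:4) {
      idx <- (off + ks[b] - new_lo + 1L):(off + ks[b] - new_lo + length(cur))
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new
    off <- new_lo
  }
  # upper-tail p for each integer score: P(S_int >= k)
  tail_p <- rev(cumsum(rev(cur)))
  list(S = S, K = K, bin = bin, lattice_offset = off, tail = tail_p,
       background = background)
}

# p-value of an integer lattice score under the model
pwm_tail_p <- function(model, k_int) {
  idx <- k_int - model$lattice_offset + 1L
  n <- length(model$tail)
  out <- numeric(length(k_int))
  out[idx <= 0] <- 1
  out[idx > n] <- 0
  ok <- idx > 0 & idx <= n
  out[ok] <- model$tail[idx[ok]]
  out
}

revcomp_pwm <- function(pwm) {
  m <- pwm[rev(seq_len(nrow(pwm))), rev(seq_len(ncol(pwm))), drop = FALSE]
  colnames(m) <- DNA_BASES
  m
}

scan_one_strand <- function(model, codes, strand) {
  L <- nrow(model$K)
  n <- length(codes)
  if (n < L) return(NULL)
  starts <- seq_len(n - L + 1L)
  idx_row <- seq_len(L)
  score <- vapply(starts, function(s) {
    w <- codes[s:(s + L - 1L)]
    if (anyNA(w)) return(NA_real_)
    sum(model$S[cbind(idx_row, w)])
  }, numeric(1))
  kint <- vapply(starts, function(s) {
    w <- codes[s:(s + L - 1L)]
    if (anyNA(w)) return(NA_integer_)
    as.integer(sum(model$K[cbind(idx_row, w)]))
  }, integer(1))
  ok <- !is.na(score)
  if (!any(ok)) return(NULL)
  tibble(offset = starts[ok] - 1L, strand = strand,
         score = score[ok], p = pwm_tail_p(model, kint[ok]))
}

#' Scan a sequence with a PWM using exact score-distribution p-values
#'
#' Scores every window on both strands with the log-odds of the PWM
#' (probabilities floored at `floor_prob` and renormalized) against a
#' 0-order background. The p-value of a window score is the exact upper
#' tail of the score distribution over i.i.d. background sequences,
#' computed by dynamic programming on a discretized score lattice (bin
#' width `bin` bits). Windows with `p <= p_threshold` are reported.
#'
#' @param pwm L x 4 probability matrix (columns A, C, G, T).
#' @param sequence DNA string to scan.
#' @param background Background base frequencies (A, C, G, T).
#' @param p_threshold Hit threshold on the p-value (default 1e-4).
#' @param floor_prob Pseudo-probability floor applied before log-odds.
#' @param bin Score lattice bin width in bits (<= 0.01).
#' @return Tibble `offset` (0-based window start on the given sequence),
#'   `strand`, `score` (bits), `p`, filtered to `p <= p_threshold`.
#' @export
pwm_scan <- function(pwm, sequence, background = rep(0.25, 4),
                     p_threshold = 1e-4, floor_prob = 1e-3, bin = 0.005) {
  sequence <- toupper(sequence)
  empty <- tibble(offset = integer(), strand = character(),
                  score = numeric(), p = numeric())
  if (nchar(sequence) < nrow(pwm)) return(empty)
  codes <- match(strsplit(sequence, "")[[1]], DNA_BASES)
  fwd <- pwm_score_model(pwm, background, floor_prob, bin)
  rev_model <- pwm_score_model(revcomp_pwm(pwm), background, floor_prob, bin)
  hits <- bind_rows(
    scan_one_strand(fwd, codes, "+"),
    scan_one_strand(rev_model, codes, "-")
  )
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits |> filter(.data$p <= p_threshold) |> arrange(.data$offset)
}

#' Scan many THS sequences with a motif collection
#'
#' @param seqs Tibble with `ths_id` and `seq` columns.
#' @param motifs Motif tibble (`motif_id`, `pwm` list-column), e.g. from
#'   [read_meme_motifs()].
#' @inheritParams pwm_scan
#' @return Hit tibble `motif_id`, `ths_id`, `offset`, `strand`, `score`,
#'   `p`.
#' @export
scan_sequences <- function(seqs, motifs, background = rep(0.25, 4),
                           p_threshold = 1e-4, floor_prob = 1e-3,
                           bin = 0.005) {
  rows <- purrr::map(seq_len(nrow(motifs)), function(m) {
    pwm <- motifs$pwm[[m]]
    fwd <- pwm_score_model(pwm, background, floor_prob, bin)
    rev_model <- pwm_score_model(revcomp_pwm(pwm), background, floor_prob,
                                 bin)
    per_seq <- purrr::map(seq_len(nrow(seqs)), function(i) {
      s <- toupper(seqs$seq[i])
      if (nchar(s) < nrow(pwm)) return(NULL)
      codes <- match(strsplit(s, "")[[1]], DNA_BASES)
      h <- bind_rows(scan_one_strand(fwd, codes, "+"),
                     scan_one_strand(rev_model, codes, "-"))
      if (is.null(h) || nrow(h) == 0L) return(NULL)
      h <- filter(h, .data$p <= p_threshold)
      if (nrow(h) == 0L) return(NULL)
      mutate(h, ths_id = seqs$ths_id[i])
    })
    h <- bind_rows(per_seq)
    if (nrow(h) == 0L) return(NULL)
    mutate(h, motif_id = motifs$motif_id[m])
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(motif_id = character(), ths_id = character(),
                  offset = integer(), strand = character(),
                  score = numeric(), p = numeric()))
  }
  select(out, "motif_id", "ths_id", "offset", "strand", "score", "p")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by full enumeration with fixed margins: the sum of
#' hypergeometric probabilities of all tables at most as probable as the
#' observed one. The odds ratio is the cross-product `ad / bc` (`Inf` when
#' `bc = 0` and `ad > 0`).
#'
#' @param a,b,c,d Non-negative integer cells, rows = condition, columns =
#'   outcome.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || !is_whole(cells)) {
    abort("cells must be non-negative integers")
  }
  if (sum(cells) == 0) return(list(odds_ratio = NaN, p = 1))
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  # relative slack so mathematically tied tables are not excluded by
  # floating-point noise
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p = min(p, 1))
}

#' Motif enrichment in foreground vs background sequences
#'
#' For each motif, counts sequences with at least one hit in the
#' foreground and background sets, tests the 2x2 table with
#' [fisher_exact_2x2()], and corrects across motifs with
#' Benjamini-Hochberg.
#'
#' @param fg_seqs,bg_seqs Tibbles with `ths_id`, `seq`.
#' @param motifs Motif tibble.
#' @inheritParams pwm_scan
#' @return Tibble `motif_id`, `fg_with`, `fg_total`, `bg_with`,
#'   `bg_total`, `odds_ratio`, `p`, `fdr`.
#' @export
motif_enrichment <- function(fg_seqs, bg_seqs, motifs,
                             background = rep(0.25, 4), p_threshold = 1e-4) {
  stopifnot(nrow(fg_seqs) > 0L, nrow(bg_seqs) > 0L)
  fg_hits <- scan_sequences(fg_seqs, motifs, background, p_threshold)
  bg_hits <- scan_sequences(bg_seqs, motifs, background, p_threshold)
  rows <- purrr::map(motifs$motif_id, function(m) {
    fw <- dplyr::n_distinct(fg_hits$ths_id[fg_hits$motif_id == m])
    bw <- dplyr::n_distinct(bg_hits$ths_id[bg_hits$motif_id == m])
    ft <- fisher_exact_2x2(fw, nrow(fg_seqs) - fw, bw, nrow(bg_seqs) - bw)
    tibble(motif_id = m, fg_with = fw, fg_total = nrow(fg_seqs),
           bg_with = bw, bg_total = nrow(bg_seqs),
           odds_ratio = ft$odds_ratio, p = ft$p)
  })
  out <- bind_rows(rows)
  mutate(out, fdr = bh_adjust(.data$p))
}

#' Build the TF-to-target regulatory network
#'
#' One edge per (TF, target gene) pair per THS: a motif hit in a THS with
#' an assigned target gene becomes an edge, deduplicated keeping the
#' best-scoring hit. Hits in THSs without a target are dropped and counted
#' in attribute `n_dropped`.
#'
#' @param hits Motif hit tibble from [scan_sequences()].
#' @param ths_target_map Tibble `ths_id`, `gene_id`.
#' @param tf_annotation Optional tibble `motif_id`, `tf` mapping motifs to
#'   TF (family) names; unannotated motifs keep their motif id.
#' @return Edge tibble `tf`, `target_gene_id`, `via_ths_id`, `score`, `p`.
#' @export
build_network <- function(hits, ths_target_map, tf_annotation = NULL) {
  h <- left_join(hits, ths_target_map, by = "ths_id")
  dropped <- sum(is.na(h$gene_id))
  h <- filter(h, !is.na(.data$gene_id))
  if (!is.null(tf_annotation)) {
    h <- left_join(h, tf_annotation, by = "motif_id") |>
      mutate(tf = dplyr::coalesce(.data$tf, .data$motif_id))
  } else {
    h <- mutate(h, tf = .data$motif_id)
  }
  edges <- h |>
    group_by(.data$tf, target_gene_id = .data$gene_id,
             via_ths_id = .data$ths_id) |>
    arrange(dplyr::desc(.data$score)) |>
    summarise(score = dplyr::first(.data$score), p = dplyr::first(.data$p),
              .groups = "drop") |>
    arrange(.data$tf, .data$target_gene_id, .data$via_ths_id)
  attr(edges, "n_dropped") <- dropped
  edges
}

#' Export a regulatory network to TSV and GraphML
#'
#' @param edges Edge tibble from [build_network()].
#' @param path_tsv Output path for the edge-list TSV (columns `source`,
#'   `target`, `via_ths`, `score`, `p`).
#' @param path_graphml Optional output path for GraphML (nodes carry a
#'   `type` attribute, `TF` or `target`).
#' @return `path_tsv`, invisibly.
#' @export
export_network <- function(edges, path_tsv, path_graphml = NULL) {
  tsv <- tibble(source = edges$tf, target = edges$target_gene_id,
                via_ths = edges$via_ths_id, score = edges$score,
                p = edges$p)
  readr::write_tsv(tsv, path_tsv)
  if (!is.null(path_graphml)) {
    nodes <- tibble(
      name = c(unique(edges$tf), setdiff(unique(edges$target_gene_id),
                                         unique(edges$tf))),
    )
    nodes$type <- if_else(nodes$name %in% edges$tf, "TF", "target")
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = edges$tf, to = edges$target_gene_id,
                     via_ths = edges$via_ths_id, score = edges$score,
                     p = edges$p),
      directed = TRUE, vertices = as.data.frame(nodes)
    )
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  invisible(path_tsv)
}

#' Read a network edge list written by [export_network()]
#'
#' @param path_tsv Edge-list TSV path.
#' @return Edge tibble `tf`, `target_gene_id`, `via_ths_id`, `score`, `p`.
#' @export
read_network <- function(path_tsv) {
  tsv <- readr::read_tsv(path_tsv, col_types = readr::cols())
  tibble(tf = as.character(tsv$source),
         target_gene_id = as.character(tsv$target),
         via_ths_id = as.character(tsv$via_ths),
         score = tsv$score, p = tsv$p)
}
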