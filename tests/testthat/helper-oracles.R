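# Independent brute-force oracles used to validate the package's
# algorithmic primitives.

# every ATG, walked codon by codon to its first in-frame stop
oracle_find_uorfs <- function(s, min_len = 60L, max_len = 450L) {
  s <- toupper(s)
  n <- nchar(s)
  out <- list()
  for (a in seq_len(max(0L, n - 2L))) {
    if (substr(s, a, a + 2L) != "ATG") next
    pos <- a + 3L
    while (pos + 2L <= n) {
      cod <- substr(s, pos, pos + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- pos + 3L - a
        if (len >= min_len && len <= max_len) {
          out[[length(out) + 1L]] <- data.frame(rel_start = a - 1L,
                                                length_nt = len)
        }
        break
      }
      pos <- pos + 3L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(rel_start = integer(), length_nt = integer()))
  }
  do.call(rbind, out)
}

# exhaustive recursion over all nested structures (no memoization)
oracle_max_pairs <- function(s, min_loop = 3L) {
  s <- chartr("TU", "UU", toupper(s))
  v <- strsplit(s, "")[[1]]
  pairs_ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (k > j) break
      if (pairs_ok(v[i], v[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(v))
}

# textbook step-up: q_(i) = min over j >= i of p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# two-sided Fisher p by explicit enumeration of tables with fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 + r2 == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  tab_prob <- function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }
  probs <- vapply(support, tab_prob, numeric(1))
  p_obs <- tab_prob(a)
  # same tie slack as the implementation: mathematically equal
  # probabilities count as ties despite floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# plain position-sweep THS intersection oracle: merged clusters of peak
# union that contain a position covered by every replicate
oracle_reproducible <- function(peaks, n_rep) {
  out <- list()
  for (ch in unique(peaks$chrom)) {
    sub <- peaks[peaks$chrom == ch, , drop = FALSE]
    hi <- max(sub$end)
    cov <- matrix(FALSE, nrow = hi, ncol = n_rep)
    reps <- sort(unique(sub$replicate))
    for (i in seq_len(nrow(sub))) {
      r <- match(sub$replicate[i], reps)
      cov[(sub$start[i] + 1L):sub$end[i], r] <- TRUE
    }
    any_cov <- rowSums(cov) > 0
    all_cov <- rowSums(cov) == n_rep
    pos <- 1L
    while (pos <= hi) {
      if (!any_cov[pos]) { pos <- pos + 1L; next }
      e <- pos
      while (e <= hi && any_cov[e]) e <- e + 1L
      if (length(reps) == n_rep && any(all_cov[pos:(e - 1L)])) {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = pos - 1L,
                                              end = e - 1L)
      }
      pos <- e
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal two-condition sample sheet
toy_samples <- function(n_rep = 3L) {
  tibble::tibble(
    sample = c(paste0("CK_", seq_len(n_rep)), paste0("LT_", seq_len(n_rep))),
    condition = rep(c("CK", "LT"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2L)
  )
}

# stub gene-model row: one single-exon gene on the given strand with a
# contiguous 5' UTR / CDS / 3' UTR layout starting at `offset`
toy_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                     offset = 1000L, utr5 = 100L, cds = 300L, utr3 = 80L) {
  w <- utr5 + cds + utr3
  if (strand == "+") {
    u5 <- tibble::tibble(start = offset, end = offset + utr5)
    cd <- tibble::tibble(start = offset + utr5, end = offset + utr5 + cds)
    u3 <- tibble::tibble(start = offset + utr5 + cds, end = offset + w)
  } else {
    u3 <- tibble::tibble(start = offset, end = offset + utr3)
    cd <- tibble::tibble(start = offset + utr3, end = offset + utr3 + cds)
    u5 <- tibble::tibble(start = offset + utr3 + cds, end = offset + w)
  }
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    tss = if (strand == "+") offset else offset + w - 1L,
    start = offset, end = offset + w,
    exons = list(tibble::tibble(start = offset, end = offset + w)),
    cds = list(cd), utr5 = list(u5), utr3 = list(u3)
  )
}
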