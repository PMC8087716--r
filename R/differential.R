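#' Log2 fold change with pseudocount
#'
#' @param mean_lt,mean_ck Non-negative condition means (vectorized).
#' @param pseudocount Added to both means before the ratio (default 1).
#' @return `log2((mean_lt + c) / (mean_ck + c))`.
#' @export
log2_fold_change <- function(mean_lt, mean_ck, pseudocount = 1) {
  if (any(mean_lt < 0, na.rm = TRUE) || any(mean_ck < 0, na.rm = TRUE)) {
    abort("means must be non-negative")
  }
  log2((mean_lt + pseudocount) / (mean_ck + pseudocount))
}

#' Two-sample t-test (Welch by default)
#'
#' Closed-form Welch t with Satterthwaite degrees of freedom, or the pooled
#' equal-variance form when `equal_var = TRUE`. When both groups have zero
#' variance and equal means the test is degenerate and `p = 1` is returned;
#' zero variance with unequal means gives `p = 0`.
#'
#' @param x,y Numeric vectors of replicate values (each of length >= 2).
#' @param equal_var Use the pooled-variance (classical Student) form.
#' @return List with `t` and two-sided `p`.
#' @export
welch_t_test <- function(x, y, equal_var = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  res <- row_t_test(matrix(x, nrow = 1), matrix(y, nrow = 1),
                    equal_var = equal_var)
  list(t = res$t[1], p = res$p[1])
}

# Vectorized row-wise two-sample t across a gene-by-replicate matrix pair.
row_t_test <- function(X, Y, equal_var = FALSE) {
  n1 <- ncol(X); n2 <- ncol(Y)
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  if (equal_var) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (m1 == m2)
    t[eq] <- 0; p[eq] <- 1
    ne <- degen & (m1 != m2)
    t[ne] <- sign(m1 - m2)[ne] * Inf
    p[ne] <- 0
  }
  list(t = t, p = p, df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Step-up adjusted q-values in the original order, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is `up` when `log2fc >= log2(fc_threshold)` and
#' `fdr < fdr_threshold`, `down` when `log2fc <= -log2(fc_threshold)` and
#' `fdr < fdr_threshold`, otherwise `ns`. The fold-change boundary is
#' inclusive (exactly 2-fold is significant at the default threshold).
#'
#' @param diff Tibble with `log2fc` and `fdr` columns.
#' @param fc_threshold Fold-change threshold on the linear scale (default 2).
#' @param fdr_threshold FDR threshold (default 0.05, strict inequality).
#' @return Input with a `call` column (`up` / `down` / `ns`) added.
#' @export
call_degs <- function(diff, fc_threshold = 2, fdr_threshold = 0.05) {
  lfc <- log2(fc_threshold)
  mutate(diff, call = dplyr::case_when(
    .data$log2fc >= lfc & .data$fdr < fdr_threshold ~ "up",
    .data$log2fc <= -lfc & .data$fdr < fdr_threshold ~ "down",
    TRUE ~ "ns"
  ))
}

#' Five-group joint transcription/translation classification
#'
#' Genes are partitioned by their DEG calls at the two levels:
#' significant only at RNA -> `transcription`; only at Ribo ->
#' `translation`; both, same direction -> `homodirectional`; both,
#' opposite directions -> `opposite`; neither -> `unchanged`.
#'
#' @param call_rna,call_ribo Character vectors of `up` / `down` / `ns`
#'   calls (vectorized, equal length).
#' @return Character vector of group labels.
#' @export
classify_five_groups <- function(call_rna, call_ribo) {
  stopifnot(length(call_rna) == length(call_ribo))
  sig_rna <- call_rna != "ns"
  sig_ribo <- call_ribo != "ns"
  dplyr::case_when(
    sig_rna & !sig_ribo ~ "transcription",
    !sig_rna & sig_ribo ~ "translation",
    sig_rna & sig_ribo & call_rna == call_ribo ~ "homodirectional",
    sig_rna & sig_ribo ~ "opposite",
    TRUE ~ "unchanged"
  )
}

FIVE_GROUPS <- c("transcription", "translation", "homodirectional",
                 "opposite", "unchanged")

#' Summarise the five-group partition
#'
#' @param labels Character vector of group labels, or a named vector of
#'   counts per group.
#' @return Tibble `group`, `n`, `pct` (percentage of classified genes to 2
#'   decimals), all five groups always present.
#' @export
group_summary <- function(labels) {
  if (!is.null(names(labels)) && is.numeric(labels)) {
    counts <- setNames(rep(0, 5), FIVE_GROUPS)
    counts[names(labels)] <- labels
  } else {
    if (length(labels) == 0L) abort("no group labels supplied")
    counts <- table(factor(labels, levels = FIVE_GROUPS))
  }
  total <- sum(counts)
  if (total == 0) abort("no classified genes")
  tibble(group = FIVE_GROUPS, n = as.numeric(counts),
         pct = percent_of(as.numeric(counts), total))
}

#' TE change classification between conditions
#'
#' `increased` when `te_lt / te_ck >= fc_threshold`, `decreased` when
#' `<= 1 / fc_threshold` (both boundaries inclusive), otherwise
#' `unchanged`. Genes with undefined TE in either condition are excluded
#' from the three classes and counted in attribute `n_undefined`.
#'
#' @param te Tibble with `gene_id`, `te_ck`, `te_lt` (NA = undefined).
#' @param fc_threshold Fold-change threshold on the TE ratio (default 2).
#' @return Tibble `gene_id`, `te_ck`, `te_lt`, `te_class` for genes with
#'   defined TE in both conditions; attribute `n_undefined` counts the rest.
#' @export
te_differential <- function(te, fc_threshold = 2) {
  undef <- is.na(te$te_ck) | is.na(te$te_lt)
  kept <- te[!undef, , drop = FALSE]
  out <- mutate(kept, te_class = dplyr::case_when(
    .data$te_lt / .data$te_ck >= fc_threshold ~ "increased",
    .data$te_lt / .data$te_ck <= 1 / fc_threshold ~ "decreased",
    TRUE ~ "unchanged"
  ))
  attr(out, "n_undefined") <- sum(undef)
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y Paired numeric vectors (>= 3 values).
#' @return Correlation in `[-1, 1]`, or NA with a warning when either
#'   vector has zero variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "pearson")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; `p` comes
#' from the asymptotic Kolmogorov distribution.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  res <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Median-of-ratios size factors
#'
#' Composition-robust per-sample scaling factors: the median across genes
#' of the ratio of a sample's counts to the per-gene geometric mean,
#' using genes with nonzero counts in every sample. Factors are scaled to
#' a geometric mean of 1.
#'
#' @param counts Count tibble (`feature_id` plus sample columns).
#' @return Named numeric vector of size factors.
#' @export
estimate_size_factors <- function(counts) {
  mat <- as.matrix(counts[, setdiff(names(counts), "feature_id")])
  keep <- rowSums(mat == 0) == 0
  if (sum(keep) < 10L) {
    warn("too few all-nonzero genes; falling back to column-sum scaling")
    sf <- colSums(mat)
    return(sf / exp(mean(log(sf))))
  }
  lmat <- log(mat[keep, , drop = FALSE])
  loggeo <- rowMeans(lmat)
  sf <- exp(apply(lmat - loggeo, 2, stats::median))
  sf / exp(mean(log(sf)))
}

#' Differential expression at one level from a count table
#'
#' The statistical kernel: per-gene condition means of FPKM, log2 fold
#' change with pseudocount 1, a two-sample t-test (Welch by default) on
#' `log2(FPKM + 1)` across replicates, Benjamini-Hochberg FDR, and DEG
#' calls at `|FC| >= fc_threshold` and `fdr < fdr_threshold`.
#'
#' @param counts Count tibble (`feature_id` plus sample columns).
#' @param samples Sample sheet covering the count columns; conditions must
#'   be `ref_condition` and one other.
#' @param lengths Feature lengths in nt (named vector or tibble).
#' @param ref_condition Baseline condition (default `"CK"`).
#' @param normalization `"size_factors"` (default) scales samples by
#'   composition-robust median-of-ratios factors before the FPKM
#'   transform, which keeps fold changes unbiased when a large share of
#'   genes shift in one direction; `"column_sums"` uses plain per-sample
#'   totals.
#' @param level Label stored on the result (`"rna"`, `"ribo"`, ...).
#' @param equal_var Use the pooled-variance t-test instead of Welch.
#' @param fc_threshold,fdr_threshold DEG thresholds passed to [call_degs()].
#' @return A `chill_diff` tibble: `gene_id`, `mean_ck`, `mean_lt`,
#'   `log2fc`, `t`, `p`, `fdr`, `call`.
#' @export
diff_expression <- function(counts, samples, lengths, ref_condition = "CK",
                            normalization = c("size_factors",
                                              "column_sums"),
                            level = "rna", equal_var = FALSE,
                            fc_threshold = 2, fdr_threshold = 0.05) {
  normalization <- match.arg(normalization)
  fpkm <- if (normalization == "size_factors") {
    sf <- estimate_size_factors(counts)
    tot <- colSums(as.matrix(counts[, names(sf)]))
    libs <- sf * exp(mean(log(tot)))
    compute_fpkm(counts, lengths, library_sizes = libs)
  } else {
    compute_fpkm(counts, lengths)
  }
  conds <- unique(samples$condition)
  stopifnot(length(conds) == 2L, ref_condition %in% conds)
  alt <- setdiff(conds, ref_condition)
  ck_samples <- samples$sample[samples$condition == ref_condition]
  lt_samples <- samples$sample[samples$condition == alt]
  X <- as.matrix(fpkm[, lt_samples, drop = FALSE])
  Y <- as.matrix(fpkm[, ck_samples, drop = FALSE])
  tt <- row_t_test(log2(X + 1), log2(Y + 1), equal_var = equal_var)
  out <- tibble(
    gene_id = fpkm$feature_id,
    mean_ck = rowMeans(Y),
    mean_lt = rowMeans(X),
    log2fc = log2_fold_change(rowMeans(X), rowMeans(Y)),
    t = tt$t,
    p = tt$p,
    fdr = bh_adjust(tt$p)
  )
  out <- call_degs(out, fc_threshold = fc_threshold,
                   fdr_threshold = fdr_threshold)
  class(out) <- c("chill_diff", class(out))
  attr(out, "level") <- level
  attr(out, "conditions") <- c(ref = ref_condition, alt = alt)
  attr(out, "thresholds") <- c(fc = fc_threshold, fdr = fdr_threshold)
  out
}

#' @export
tidy.chill_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "chill_diff")
  mutate(out, level = attr(x, "level"))
}

#' @export
glance.chill_diff <- function(x, ...) {
  tibble(
    level = attr(x, "level"),
    n_genes = nrow(x),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    n_ns = sum(x$call == "ns")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
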