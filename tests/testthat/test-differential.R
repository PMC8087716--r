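test_that("log2 fold change uses the pseudocount floor", {
  expect_equal(log2_fold_change(8, 8), 0)
  expect_equal(log2_fold_change(31, 7), 2)
  expect_equal(log2_fold_change(0, 0), 0)
  expect_error(log2_fold_change(-1, 5), "non-negative")
})

test_that("the Welch t-test matches stats::t.test and its edge rules", {
  x <- c(1.1, 2.4, 3.2, 2.0)
  y <- c(2.2, 4.5, 3.3)
  got <- welch_t_test(x, y)
  ref <- t.test(x, y)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  pooled <- welch_t_test(x, y, equal_var = TRUE)
  ref2 <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$p, ref2$p.value, tolerance = 1e-12)

  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_lt(welch_t_test(c(1, 2, 3), c(101, 102, 103))$p, 0.001)

  # symmetry: swapping the groups negates t, keeps p
  sw <- welch_t_test(y, x)
  expect_equal(sw$t, -got$t)
  expect_equal(sw$p, got$p)

  # degenerate zero-variance cases
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_t_test(c(2, 2), c(3, 3))$p, 0)
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(5)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calls apply the inclusive fold-change rule", {
  d <- tibble::tibble(log2fc = c(1.5, 1.5, 0.9, -1, 1),
                      fdr = c(0.01, 0.06, 0.001, 0.04, 0.05))
  out <- call_degs(d)
  expect_equal(out$call, c("up", "ns", "ns", "down", "ns"))
})

test_that("five-group classification partitions all call combinations", {
  expect_equal(classify_five_groups("up", "ns"), "transcription")
  expect_equal(classify_five_groups("ns", "down"), "translation")
  expect_equal(classify_five_groups("down", "down"), "homodirectional")
  expect_equal(classify_five_groups("up", "down"), "opposite")
  expect_equal(classify_five_groups("ns", "ns"), "unchanged")
  combos <- expand.grid(rna = c("up", "down", "ns"),
                        ribo = c("up", "down", "ns"),
                        stringsAsFactors = FALSE)
  lab <- classify_five_groups(combos$rna, combos$ribo)
  expect_true(all(lab %in% c("transcription", "translation",
                             "homodirectional", "opposite", "unchanged")))
  expect_false(any(is.na(lab)))
})

test_that("group summaries report two-decimal percentages that sum to 100", {
  gs <- group_summary(c(transcription = 4842, translation = 3010,
                        homodirectional = 2569, opposite = 305,
                        unchanged = 33053))
  expect_equal(gs$pct[gs$group == "transcription"], 11.06)
  expect_equal(gs$pct[gs$group == "translation"], 6.88)
  expect_lt(abs(sum(gs$pct) - 100), 0.05)
  gs1 <- group_summary(c(transcription = 1, translation = 0,
                         homodirectional = 0, opposite = 0, unchanged = 0))
  expect_equal(gs1$pct[1], 100)
  expect_error(group_summary(character(0)), "no group labels")
})

test_that("TE differential uses inclusive two-fold boundaries", {
  te <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                       te_ck = c(1, 2, 2, NA),
                       te_lt = c(2, 2, 0.999, 1))
  out <- te_differential(te)
  expect_equal(out$te_class, c("increased", "unchanged", "decreased"))
  expect_equal(attr(out, "n_undefined"), 1L)
})

test_that("Pearson and KS wrappers behave per contract", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 3, 2)), 0.5)
  expect_warning(r <- pearson_r(c(1, 1, 1), x), "zero variance")
  expect_true(is.na(r))

  expect_equal(ks_two_sample(x, x)$D, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$D, 0.5)
})

test_that("size factors undo composition bias from planted shifts", {
  set.seed(9)
  n <- 500
  mu <- rlnorm(n, log(200), 1)
  # 40% of genes shifted 8x, signs balanced as in the planted design
  shift <- c(rep(8, 100), rep(1 / 8, 100), rep(1, 300))
  counts <- tibble::tibble(feature_id = sprintf("g%03d", 1:n))
  for (s in paste0("CK_", 1:3)) counts[[s]] <- rnbinom(n, mu = mu, size = 10)
  for (s in paste0("LT_", 1:3)) {
    counts[[s]] <- rnbinom(n, mu = mu * shift, size = 10)
  }
  sf <- estimate_size_factors(counts)
  # unshifted genes dominate the median: CK and LT factors stay close
  expect_lt(max(sf) / min(sf), 1.3)
  d <- diff_expression(counts, toy_samples(), setNames(rep(1000, n),
                                                       counts$feature_id))
  null_lfc <- d$log2fc[201:500]
  expect_lt(abs(median(null_lfc)), 0.2)
  # plain column-sum normalization is visibly biased on the same data by
  # the linear-scale asymmetry of 8x vs 1/8x shifts
  d2 <- diff_expression(counts, toy_samples(),
                        setNames(rep(1000, n), counts$feature_id),
                        normalization = "column_sums")
  expect_gt(abs(median(d2$log2fc[201:500])), abs(median(null_lfc)))
})

test_that("the diff object supports tidy, glance and autoplot", {
  set.seed(10)
  n <- 60
  counts <- tibble::tibble(feature_id = sprintf("g%02d", 1:n))
  for (s in toy_samples()$sample) {
    counts[[s]] <- rnbinom(n, mu = 100, size = 10)
  }
  d <- diff_expression(counts, toy_samples(),
                       setNames(rep(1000, n), counts$feature_id))
  td <- tidy(d)
  expect_s3_class(td, "tbl_df")
  expect_true("level" %in% names(td))
  gl <- glance(d)
  expect_equal(gl$n_genes, n)
  expect_equal(gl$n_up + gl$n_down + gl$n_ns, n)
  p <- ggplot2::autoplot(d)
  expect_s3_class(p, "ggplot")
})
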