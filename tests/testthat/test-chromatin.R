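mk_peaks <- function(...) {
  # each argument: list(chrom, start, end, replicate)
  dplyr::bind_rows(lapply(list(...), function(x) {
    tibble::tibble(chrom = x[[1]], start = x[[2]], end = x[[3]],
                   replicate = x[[4]])
  }))
}

test_that("reproducible THSs require all-replicate support", {
  p <- mk_peaks(list("chr1", 100L, 200L, "r1"),
                list("chr1", 100L, 200L, "r2"),
                list("chr1", 100L, 200L, "r3"))
  ths <- reproducible_ths(p)
  expect_equal(nrow(ths), 1L)
  expect_equal(c(ths$start, ths$end), c(100L, 200L))

  # present in only 2 of 3 replicates: dropped
  p2 <- dplyr::bind_rows(p, mk_peaks(list("chr1", 500L, 600L, "r1"),
                                     list("chr1", 500L, 600L, "r2")))
  expect_equal(nrow(reproducible_ths(p2)), 1L)

  # chained overlaps merge into the union when a common position exists
  p3 <- mk_peaks(list("chr1", 100L, 200L, "r1"),
                 list("chr1", 150L, 250L, "r2"),
                 list("chr1", 180L, 300L, "r3"))
  ths <- reproducible_ths(p3)
  expect_equal(c(ths$start, ths$end), c(100L, 300L))

  expect_warning(out <- reproducible_ths(p[0, ]), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("reproducible THSs match the position-sweep oracle", {
  set.seed(21)
  for (i in 1:150) {
    n_rep <- sample(2:4, 1)
    peaks <- dplyr::bind_rows(lapply(seq_len(n_rep), function(r) {
      k <- sample(1:6, 1)
      start <- sample(0:400, k)
      tibble::tibble(chrom = sample(c("c1", "c2"), k, replace = TRUE),
                     start = start,
                     end = start + sample(10:80, k, replace = TRUE),
                     replicate = paste0("r", r))
    }))
    got <- reproducible_ths(peaks, n_replicates = n_rep)
    want <- oracle_reproducible(peaks, n_rep)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got[, c("chrom", "start", "end")],
                   tibble::as_tibble(want), ignore_attr = TRUE)
    }
  }
})

test_that("condition overlap counts partition each THS set", {
  a <- tibble::tibble(chrom = "c1", start = c(0L, 300L), end = c(100L, 400L))
  ov <- condition_overlap(a, a)
  n <- setNames(ov$n, ov$set)
  expect_equal(unname(n["shared_ck"]), 2)
  expect_equal(unname(n["ck_only"]), 0)

  b <- tibble::tibble(chrom = "c1", start = 1000L, end = 1100L)
  ov <- condition_overlap(a, b)
  n <- setNames(ov$n, ov$set)
  expect_equal(unname(n[c("shared_ck", "ck_only", "lt_only")]), c(0, 2, 1))

  # 1 bp overlap counts at the default threshold
  a1 <- tibble::tibble(chrom = "c1", start = 0L, end = 100L)
  b1 <- tibble::tibble(chrom = "c1", start = 99L, end = 200L)
  ov <- condition_overlap(a1, b1)
  expect_equal(ov$n[ov$set == "shared_ck"], 1)
  ov2 <- condition_overlap(a1, tibble::tibble(chrom = "c1", start = 100L,
                                              end = 200L))
  expect_equal(ov2$n[ov2$set == "shared_ck"], 0)
})

test_that("THS annotation uses midpoint categories with promoter priority", {
  models <- dplyr::bind_rows(
    toy_gene("gA", strand = "+", offset = 10000L),
    toy_gene("gC", strand = "-", offset = 28000L), # promoter [28480,30480)
    toy_gene("gD", strand = "+", offset = 30000L)  # exon [30000,30480)
  )
  ths <- tibble::tibble(
    ths_id = c("t1", "t2", "t3", "t4"),
    chrom = "chr1",
    start = c(8400L, 10050L, 50000L, 30090L),
    end = c(8600L, 10150L, 50200L, 30110L)
  )
  ann <- annotate_ths(ths, models)
  # t1 midpoint 8500: 1500 bp upstream of gA's TSS (10000)
  expect_equal(ann$category[1], "promoter")
  expect_equal(ann$nearest_gene_id[1], "gA")
  expect_equal(ann$distance_to_tss[1], -1500)
  # t2 midpoint inside gA exon
  expect_equal(ann$category[2], "exon")
  expect_false(ann$is_distal[2])
  # t3 midpoint 50100: far from everything
  expect_equal(ann$category[3], "distal_intergenic")
  expect_true(ann$is_distal[3])
  # t4 midpoint 30100: inside gD's exon but also in gC's promoter window
  # (2 kb upstream of the minus-strand TSS) -> promoter by priority
  expect_equal(ann$category[4], "promoter")

  # unknown chromosome: distal with undefined nearest gene
  ann2 <- annotate_ths(tibble::tibble(ths_id = "x", chrom = "chrZ",
                                      start = 0L, end = 10L), models)
  expect_equal(ann2$category, "distal_intergenic")
  expect_true(is.na(ann2$nearest_gene_id))
})

test_that("cold-induced calling enforces presence, fold-change and p rules", {
  samples <- tibble::tibble(
    sample = c(paste0("ATAC_CK_", 1:3), paste0("ATAC_LT_", 1:3)),
    condition = rep(c("CK", "LT"), each = 3), replicate = rep(1:3, 2))
  ths_ck <- tibble::tibble(ths_id = "ck1", chrom = "c1",
                           start = 1000L, end = 1400L)
  ths_lt <- tibble::tibble(
    ths_id = c("lt1", "lt2", "lt3"), chrom = "c1",
    start = c(1399L, 5000L, 9000L), end = c(1800L, 5400L, 9400L))
  set.seed(61)
  bg_start <- seq(20000L, 42000L, by = 2000L) # 12 unshifted background sites
  bg <- tibble::tibble(chrom = "c1", start = bg_start, end = bg_start + 400L)
  for (s in c(paste0("ATAC_CK_", 1:3), paste0("ATAC_LT_", 1:3))) {
    bg[[s]] <- rnbinom(nrow(bg), mu = 150, size = 10)
  }
  counts <- dplyr::bind_rows(tibble::tibble(
    chrom = "c1", start = c(1399L, 5000L, 9000L),
    end = c(1800L, 5400L, 9400L),
    ATAC_CK_1 = c(100L, 40L, 100L), ATAC_CK_2 = c(110L, 38L, 105L),
    ATAC_CK_3 = c(95L, 42L, 98L),
    ATAC_LT_1 = c(800L, 320L, 101L), ATAC_LT_2 = c(820L, 305L, 99L),
    ATAC_LT_3 = c(790L, 330L, 102L)), bg)
  res <- cold_induced_ths(ths_lt, ths_ck, counts, samples)
  # lt1 overlaps a CK THS by 1 bp: excluded before testing
  expect_false("lt1" %in% res$ths_id)
  # lt2: 8x enrichment -> called
  expect_true(res$cold_induced[res$ths_id == "lt2"])
  # lt3: equal counts -> fails the fold-change rule
  expect_false(res$cold_induced[res$ths_id == "lt3"])
})

test_that("distal target assignment follows the closest-downstream rule", {
  # THS between two (+) genes: 3 kb before B's TSS, far past A
  models <- dplyr::bind_rows(
    toy_gene("gA", strand = "+", offset = 10000L),
    toy_gene("gB", strand = "+", offset = 43500L)
  )
  ths <- tibble::tibble(ths_id = "t", chrom = "chr1",
                        start = 40400L, end = 40600L)
  tg <- assign_distal_targets(ths, models)
  expect_equal(tg$gene_id, "gB")
  expect_equal(tg$distance, 3000)
  expect_true(tg$downstream)

  # (-) gene starting 2 kb left vs (+) gene starting 8 kb right: both
  # downstream in orientation, the closer (-) gene wins
  w <- 480L
  models2 <- dplyr::bind_rows(
    toy_gene("gMinus", strand = "-", offset = 40000L - 2000L - w),
    toy_gene("gPlus", strand = "+", offset = 48000L)
  )
  ths2 <- tibble::tibble(ths_id = "t", chrom = "chr1",
                         start = 39900L, end = 40100L)
  tg2 <- assign_distal_targets(ths2, models2)
  expect_equal(tg2$gene_id, "gMinus")

  # symmetric tie: lexicographically smaller gene id
  models3 <- dplyr::bind_rows(
    toy_gene("gB", strand = "-", offset = 40000L - 5000L - w),
    toy_gene("gA", strand = "-", offset = 40000L - 5000L - w)
  )
  models3$gene_id <- c("gB", "gA")
  ths3 <- tibble::tibble(ths_id = "t", chrom = "chr1",
                         start = 39900L, end = 40100L)
  expect_equal(assign_distal_targets(ths3, models3)$gene_id, "gA")
})

test_that("target responsiveness is the non-unchanged fraction", {
  labels <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:318),
    group = c(rep("transcription", 40), rep("translation", 20),
              rep("homodirectional", 10), rep("opposite", 1),
              rep("unchanged", 247))
  )
  out <- crosscheck_targets(labels$gene_id, labels)
  expect_equal(out$n_responsive, 71L)
  expect_equal(out$pct_responsive, 22.33)
  expect_equal(crosscheck_targets("g300", labels)$pct_responsive, 0)
  expect_equal(crosscheck_targets(c("g001", "g002"),
                                  labels)$pct_responsive, 100)
  expect_error(crosscheck_targets(character(0), labels), "empty")
})

test_that("set enrichment gives hypergeometric upper-tail p-values", {
  universe <- sprintf("g%02d", 1:20)
  term_map <- tibble::tibble(term = "T1", gene_id = universe[1:5])
  # set identical to the term: minimal possible p = 1 / C(20, 5)
  res <- set_enrichment(universe[1:5], term_map, universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # disjoint set: overlap 0 -> upper tail = 1
  res <- set_enrichment(universe[6:10], term_map, universe)
  expect_equal(res$p, 1)
  # universe equal to the term
  res <- set_enrichment(universe[1:3], tibble::tibble(term = "T", gene_id = universe),
                        universe)
  expect_equal(res$p, 1)
})
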