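point_pwm <- function(consensus, strength = 1) {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - strength) / 3, nrow = length(bases), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(bases)) m[i, bases[i]] <- strength
  m
}

test_that("PWM log-odds scores match the floored closed form", {
  pwm <- point_pwm("ACGT")
  hits <- pwm_scan(pwm, "ACGT", p_threshold = 1)
  fwd <- hits[hits$strand == "+", ]
  # flooring 1e-3 then renormalizing: dominant prob 1/1.003
  expected <- 4 * log2((1 / 1.003) / 0.25)
  expect_equal(fwd$score, expected, tolerance = 1e-9)
  expect_equal(fwd$offset, 0L)
})

test_that("scans return no hits above threshold and respect length", {
  pwm <- point_pwm("ACGTAC")
  expect_equal(nrow(pwm_scan(pwm, "TTTTTTTTTT", p_threshold = 1e-4)), 0L)
  expect_equal(nrow(pwm_scan(pwm, "ACG")), 0L) # motif longer than sequence
})

test_that("scanning is strand-symmetric", {
  set.seed(41)
  pwm <- point_pwm("TTTGACCT", strength = 0.9)
  s <- paste0(rand_seq(30), "TTTGACCT", rand_seq(30))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h1 <- pwm_scan(pwm, s, p_threshold = 1e-3)
  h2 <- pwm_scan(pwm, rc, p_threshold = 1e-3)
  expect_equal(nrow(h1), nrow(h2))
  # offsets mirror: offset' = len - len(motif) - offset, strands flip
  L <- nchar(s)
  w <- nrow(pwm)
  mirrored <- sort(L - w - h2$offset)
  expect_equal(sort(h1$offset), mirrored)
  expect_equal(sort(h1$score), sort(h2$score))
  expect_equal(sort(h1$p), sort(h2$p))
})

test_that("lattice p-values agree with exhaustive window enumeration", {
  set.seed(42)
  for (L in c(5L, 8L)) {
    pwm <- matrix(stats::rgamma(L * 4, 1), nrow = L)
    pwm <- pwm / rowSums(pwm)
    colnames(pwm) <- c("A", "C", "G", "T")
    model <- chillomics:::pwm_score_model(pwm, rep(0.25, 4), 1e-3, 0.005)
    # all 4^L windows
    grid <- as.matrix(expand.grid(rep(list(1:4), L)))
    real_scores <- rowSums(matrix(model$S[cbind(rep(1:L, each = nrow(grid)),
                                                as.vector(grid))],
                                  nrow = nrow(grid)))
    int_scores <- rowSums(matrix(model$K[cbind(rep(1:L, each = nrow(grid)),
                                               as.vector(grid))],
                                 nrow = nrow(grid)))
    # integerized enumeration must match the DP exactly
    ks <- sort(unique(int_scores))
    for (k in sample(ks, min(20, length(ks)))) {
      expect_equal(chillomics:::pwm_tail_p(model, k),
                   mean(int_scores >= k), tolerance = 1e-12)
    }
    # and bound the real-score tail within the lattice slack (one bin per
    # position)
    slack <- L * 0.005
    for (k in sample(ks, min(10, length(ks)))) {
      s_real <- k * 0.005
      p_dp <- chillomics:::pwm_tail_p(model, k)
      expect_lte(p_dp, mean(real_scores >= s_real - slack) + 1e-12)
      expect_gte(p_dp, mean(real_scores >= s_real + slack) - 1e-12)
    }
  }
})

test_that("Fisher's exact test matches enumeration and fisher.test", {
  ft <- fisher_exact_2x2(2, 0, 0, 2)
  expect_equal(ft$p, 1 / 3, tolerance = 1e-12)
  expect_equal(ft$odds_ratio, Inf)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p, 1)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0)$p, 1)

  # transposing the table leaves p unchanged
  expect_equal(fisher_exact_2x2(3, 1, 2, 5)$p,
               fisher_exact_2x2(3, 2, 1, 5)$p)

  set.seed(43)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(5:30, 1), rep(0.25, 4)))
    got <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p
    expect_equal(got, oracle_fisher_p(cells[1], cells[2], cells[3],
                                      cells[4]), tolerance = 1e-12)
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("motif enrichment flags planted motifs and respects the null", {
  set.seed(44)
  motifs <- tibble::tibble(motif_id = "M", width = 8L,
                           pwm = list(point_pwm("AGCCGCCA", 0.97)))
  fg <- tibble::tibble(ths_id = paste0("f", 1:20),
                       seq = vapply(1:20, function(i) {
                         paste0(rand_seq(40), "AGCCGCCA", rand_seq(40))
                       }, character(1)))
  bg <- tibble::tibble(ths_id = paste0("b", 1:200),
                       seq = vapply(1:200, function(i) rand_seq(88),
                                    character(1)))
  res <- motif_enrichment(fg, bg, motifs)
  expect_lt(res$p, 1e-6)
  expect_equal(res$fg_with, 20L)

  null_res <- motif_enrichment(bg[1:50, ], bg[51:200, ], motifs)
  expect_gt(null_res$p, 0.05)
})

test_that("network edges dedupe per THS and drop untargeted hits", {
  hits <- tibble::tibble(
    motif_id = c("M1", "M1", "M2"),
    ths_id = c("t1", "t1", "t2"),
    offset = c(0L, 10L, 5L), strand = "+",
    score = c(8, 12, 9), p = c(1e-5, 1e-6, 1e-5)
  )
  map <- tibble::tibble(ths_id = "t1", gene_id = "G1")
  edges <- build_network(hits, map)
  expect_equal(nrow(edges), 1L) # two hits of M1 in t1 collapse
  expect_equal(edges$score, 12) # best-scoring hit kept
  expect_equal(attr(edges, "n_dropped"), 1L) # t2 has no target

  ann <- tibble::tibble(motif_id = "M1", tf = "AP2/ERF")
  edges2 <- build_network(hits, map, ann)
  expect_equal(edges2$tf, "AP2/ERF")
})

test_that("network export round-trips TSV and writes valid GraphML", {
  edges <- tibble::tibble(
    tf = c("ERF", "WRKY", "ERF"),
    target_gene_id = c("G1", "G2", "G3"),
    via_ths_id = c("t1", "t2", "t3"),
    score = c(10, 11, 12), p = c(1e-5, 1e-6, 1e-7)
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(edges, tsv, gml)
  expect_equal(length(readLines(tsv)), 4L) # header + 3 edges
  back <- read_network(tsv)
  expect_equal(back, edges, ignore_attr = TRUE)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::V(g)$type, c("TF", "target"))

  # empty network still writes a valid header-only file
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  export_network(edges[0, ], tsv2)
  expect_equal(length(readLines(tsv2)), 1L)
})
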