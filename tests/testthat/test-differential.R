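de_fixture <- function(values_a, values_b, gene = "g1") {
  n_a <- length(values_a); n_b <- length(values_b)
  counts <- Matrix::Matrix(matrix(1, 2, n_a + n_b), sparse = TRUE)
  dimnames(counts) <- list(c(gene, "filler"),
                           sprintf("c%02d", seq_len(n_a + n_b)))
  meta <- data.frame(cell_id = colnames(counts), sample_id = "s1",
                     group = rep(c("DFUNH", "DS"), c(n_a, n_b)),
                     tissue = "skin", cell_type = "A", stringsAsFactors = FALSE)
  x <- labeled_expression(counts, meta)
  norm <- counts
  norm[1, ] <- c(values_a, values_b)
  norm[2, ] <- 0                      # filler gene expressed nowhere
  x$norm <- methods::as(norm, "CsparseMatrix")
  x
}

test_that("the exact branch reproduces enumeration, including the 1..6 split", {
  x <- de_fixture(c(1, 2, 3), c(4, 5, 6))
  de <- wilcoxon_de(x, "A", "DFUNH", "DS")
  expect_equal(de$p[de$gene == "g1"], 0.1)                      # C(6,3) enumeration
  expect_equal(de$p[de$gene == "g1"], enum_wilcox_p(c(1, 2, 3), c(4, 5, 6)))
  # several random tie-free draws against the brute-force oracle
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5)
    de <- wilcoxon_de(de_fixture(a, b), "A", "DFUNH", "DS")
    expect_equal(de$p[de$gene == "g1"], enum_wilcox_p(a, b), tolerance = 1e-12)
  }
})

test_that("large-sample p-values match wilcox.test on tie-free data", {
  set.seed(11)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  de <- wilcoxon_de(de_fixture(a, b), "A", "DFUNH", "DS")
  ref <- wilcox.test(a, b, correct = TRUE)$p.value
  expect_equal(de$p[de$gene == "g1"], ref, tolerance = 0.005)
})

test_that("identical distributions give p = 1 and swapping groups negates log2fc", {
  x <- de_fixture(c(1, 2, 3, 4), c(1, 2, 3, 4))
  de <- wilcoxon_de(x, "A", "DFUNH", "DS")
  expect_equal(de$p[de$gene == "g1"], 1)
  set.seed(3)
  a <- abs(rnorm(8)); b <- abs(rnorm(8, 1))
  fwd <- wilcoxon_de(de_fixture(a, b), "A", "DFUNH", "DS")
  bwd <- wilcoxon_de(de_fixture(a, b), "A", "DS", "DFUNH")
  expect_equal(fwd$p, bwd$p, tolerance = 1e-12)
  expect_equal(fwd$log2fc, -bwd$log2fc, tolerance = 1e-12)
})

test_that("log2fc back-transforms means with the +1 stabilizer", {
  # norm_a all ln 2, norm_b all 0 -> log2fc = log2(2/1) = 1
  x <- de_fixture(rep(log(2), 5), rep(0, 5))
  de <- wilcoxon_de(x, "A", "DFUNH", "DS")
  expect_equal(de$log2fc[de$gene == "g1"], 1, tolerance = 1e-12)
  # gene expressed nowhere: p = 1, log2fc = 0
  expect_equal(de$p[de$gene == "filler"], 1)
  expect_equal(de$log2fc[de$gene == "filler"], 0)
})

test_that("BH adjustment matches hand application and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, NA)), "0, 1")
})

test_that("BH matches the brute-force step-up definition on random vectors", {
  set.seed(19)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_lt(max(abs(bh_adjust(p) - brute_bh(p))), 1e-12)
  }
})

test_that("eligibility requires at least three cells in both groups", {
  meta <- data.frame(
    cell_id = sprintf("c%02d", 1:12), sample_id = "s1",
    group = c(rep("DS", 6), rep("DFUNH", 6)), tissue = "blood",
    cell_type = c("A", "A", "A", "B", "B", "Platelet",
                  "A", "A", "A", "B", "B", "B"),
    stringsAsFactors = FALSE)
  counts <- Matrix::Matrix(matrix(1, 2, 12), sparse = TRUE)
  dimnames(counts) <- list(c("g1", "g2"), meta$cell_id)
  x <- labeled_expression(counts, meta)
  elig <- eligible_cell_types(x, "DS", "DFUNH")
  expect_equal(elig, "A")                       # B has 2 in DS, platelets absent
  expect_false("Platelet" %in% elig)            # missing from one group
})

test_that("rescue DEG calling follows the two-contrast definition", {
  mk <- function(gene, ct, lfc, padj)
    data.frame(gene = gene, cell_type = ct, log2fc = lfc, p = padj, p_adj = padj)
  un <- mk(c("A", "B", "C"), "CT1", c(-0.3, -0.3, 0.1), c(0.001, 0.001, 0.5))
  he <- mk(c("A", "B", "C"), "CT1", c(0.4, 0.1, 0.4), c(0.005, 0.5, 0.005))
  sets <- call_deg_sets(un, he)
  expect_equal(sets$genes$rescue_up, "A")       # down then up, both significant
  expect_equal(sets$genes$rescue_down, character(0))
  expect_equal(sets$pairs$rescue_class[sets$pairs$gene == "B"], "none")
  # mismatched cell-type universes are refused
  he2 <- he; he2$cell_type <- "CT2"
  expect_error(call_deg_sets(un, he2), "universes")
})

test_that("planted reversal genes are recovered with high sensitivity and precision", {
  plant <- fixture_rescue_plant()
  cfg <- sim_config(proportions = fixture_dominant_props(), rescue_genes = plant)
  sim <- simulate_cohort(cfg, seed = 1)
  x <- normalize_counts(filter_cells(sim$expr)$expr)
  sets <- call_deg_sets(de_contrast(x, "DFUNH", "DS"),
                        de_contrast(x, "DFUH", "DFUNH"))
  tp <- length(intersect(sets$genes$rescue_up, plant$gene[plant$direction == "up"])) +
    length(intersect(sets$genes$rescue_down, plant$gene[plant$direction == "down"]))
  called <- length(sets$genes$rescue_up) + length(sets$genes$rescue_down)
  expect_gte(tp / 20, 0.8)
  expect_gte(tp / called, 0.8)
})

test_that("tissue-level shared rescue genes are direction-matched intersections", {
  a <- structure(list(genes = list(rescue_up = c("X", "Y"), rescue_down = "Z")),
                 class = "wr_deg_sets")
  b <- structure(list(genes = list(rescue_up = c("Y", "W"), rescue_down = "Q")),
                 class = "wr_deg_sets")
  sh <- shared_rescue_genes(a, b)
  expect_equal(sh$rescue_up, "Y")
  expect_equal(sh$rescue_down, character(0))
})
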