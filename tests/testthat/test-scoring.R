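test_that("module score is zero when all genes behave identically", {
  counts <- Matrix::Matrix(matrix(rep(c(1, 2, 4), each = 50), nrow = 50,
                                  byrow = FALSE), sparse = TRUE)
  dimnames(counts) <- list(sprintf("g%02d", 1:50), c("c1", "c2", "c3"))
  meta <- data.frame(cell_id = colnames(counts), sample_id = "s1", group = "DS",
                     tissue = "skin", cell_type = "A")
  x <- normalize_counts(labeled_expression(counts, meta))
  sc <- module_score(x, c("g01", "g07", "g30"), nbin = 5, seed = 1)
  expect_equal(unname(sc), rep(0, 3), tolerance = 1e-12)
})

test_that("a +1 shift of member genes in half the cells scores ~+1 there", {
  # members keep the background AVERAGE (so binning matches them with
  # background controls) but run +1 in the first half of cells, -1 in the rest
  set.seed(31)
  n_genes <- 1000; n_cells <- 40   # members are 2% of genes, so control
                                   # draws barely dilute the planted shift
  base <- matrix(rnorm(n_genes * n_cells, 2, 0.1), n_genes, n_cells)
  members <- sprintf("g%04d", seq(5, 100, by = 5))
  rownames(base) <- sprintf("g%04d", seq_len(n_genes))
  colnames(base) <- sprintf("c%02d", seq_len(n_cells))
  base[members, 1:20] <- base[members, 1:20] + 1
  base[members, 21:40] <- base[members, 21:40] - 1
  counts <- Matrix::Matrix(matrix(1, n_genes, n_cells,
                                  dimnames = dimnames(base)), sparse = TRUE)
  meta <- data.frame(cell_id = colnames(base), sample_id = "s1", group = "DS",
                     tissue = "skin", cell_type = "A")
  x <- labeled_expression(counts, meta)
  x$norm <- methods::as(Matrix::Matrix(base, sparse = TRUE), "CsparseMatrix")
  sc <- module_score(x, members, nbin = 10, nctrl = 50, seed = 2)
  expect_equal(mean(sc[1:20]), 1, tolerance = 0.1)
  expect_equal(mean(sc[21:40]), -1, tolerance = 0.1)
})

test_that("module scores of random sets on null data stay near zero", {
  sim <- simulate_cohort(sim_config(cells_per_sample = 60), seed = 8)
  x <- normalize_counts(filter_cells(sim$expr)$expr)
  set.seed(9)
  m <- vapply(1:20, function(i)
    mean(module_score(x, sample(rownames(x$counts), 30), seed = i)), numeric(1))
  expect_lt(mean(abs(m)), 0.05)
})

test_that("module score demands present members and enough genes", {
  x <- normalize_counts(tiny_expr())
  expect_error(module_score(x, "NOT_A_GENE"), "no member gene")
  expect_error(module_score(x, "GA", nbin = 24), "fewer genes than bins")
})

test_that("single-hit enrichment scores hit the running-sum extremes exactly", {
  ranked <- setNames(c(3, 2, 1, 0.5), c("gA", "gB", "gC", "gD"))
  expect_equal(gsea_preranked(ranked, "gA", nperm = 50, seed = 1)$es, 1.0)
  expect_equal(gsea_preranked(ranked, "gD", nperm = 50, seed = 1)$es, -1.0)
  expect_error(gsea_preranked(ranked, names(ranked)), "whole ranked list")
  expect_error(gsea_preranked(ranked, "nope"), "does not intersect")
})

test_that("ES stays in [-1, 1] and flips sign under metric negation", {
  set.seed(13)
  genes <- sprintf("G%03d", 1:200)
  for (i in 1:10) {
    metric <- setNames(rnorm(200), genes)
    set_i <- sample(genes, 15)
    es <- gsea_preranked(metric, set_i, nperm = 10, seed = i)$es
    expect_true(es >= -1 && es <= 1)
    es_neg <- gsea_preranked(-metric, set_i, nperm = 10, seed = i)$es
    expect_equal(es_neg, -es, tolerance = 1e-12)
  }
})

test_that("enrichment scores agree with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  metric <- sort(setNames(rnorm(300), sprintf("G%03d", 1:300)), decreasing = TRUE)
  for (i in 1:5) {
    set_i <- sample(names(metric), 20)
    es <- gsea_preranked(metric, set_i, nperm = 10, seed = i)$es
    ref <- fgsea::calcGseaStat(unname(metric), sort(match(set_i, names(metric))),
                               gseaParam = 1)
    expect_equal(es, ref, tolerance = 1e-6)
  }
})

test_that("random sets are rarely significant and BH batching works", {
  set.seed(21)
  metric <- setNames(rnorm(400), sprintf("G%03d", 1:400))
  sets <- lapply(1:25, function(i) sample(names(metric), 20))
  names(sets) <- paste0("S", 1:25)
  tab <- gsea_table(metric, sets, nperm = 200, seed = 4)
  expect_lte(sum(tab$significant), 2)
  expect_true(all(tab$p_adj >= tab$p))
})

test_that("DE-derived ranking filters and sorts as configured", {
  de <- data.frame(gene = c("A", "B", "C", "D"),
                   log2fc = c(2, -1.5, 0.3, 0.9),
                   p_adj = c(0.001, 0.01, 0.001, 0.2))
  r <- gsea_rank_from_de(de)
  expect_equal(names(r), c("A", "B"))          # |lfc| > 0.5 and p_adj < 0.05
  expect_equal(unname(r), c(2, -1.5))
})
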