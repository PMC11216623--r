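test_that("rescue classification matches hand-computed log ratios", {
  r <- classify_rescue(0.10, 0.05, 0.12, thr = 0.1, eps = 0)
  expect_equal(r$l1, -1, tolerance = 1e-12)
  expect_equal(r$l2, log2(0.12 / 0.05), tolerance = 1e-12)  # ~1.263
  expect_equal(r$rescue_class, "rescue_up")

  flat <- classify_rescue(0.2, 0.2, 0.2, thr = 0.1, eps = 0)
  expect_equal(c(flat$l1, flat$l2), c(0, 0))
  expect_equal(flat$rescue_class, "none")

  d <- classify_rescue(0.05, 0.10, 0.04, thr = 0.1, eps = 0)
  expect_equal(d$l1, 1, tolerance = 1e-12)
  expect_equal(d$l2, log2(0.04 / 0.10), tolerance = 1e-12)  # ~-1.322
  expect_equal(d$rescue_class, "rescue_down")

  expect_error(classify_rescue(-0.1, 0.2, 0.2), ">= 0")
  # zero proportion with eps = 0 is degenerate, never a rescue call
  z <- classify_rescue(0, 0.1, 0.2, eps = 0)
  expect_true(z$degenerate)
  expect_equal(z$rescue_class, "none")
})

test_that("rescue classes are reversal-invariant, swap under inversion, and vanish at huge thresholds", {
  set.seed(42)
  swap <- c(rescue_up = "rescue_down", rescue_down = "rescue_up", none = "none")
  for (i in 1:25) {
    p <- runif(3, 0.01, 0.5)
    fwd <- classify_rescue(p[1], p[2], p[3], thr = 0.1, eps = 0)
    # reading the trajectory backwards keeps a V a V (and a peak a peak)
    rev <- classify_rescue(p[3], p[2], p[1], thr = 0.1, eps = 0)
    expect_equal(rev$rescue_class, fwd$rescue_class)
    # inverting the proportions (negating both log ratios) swaps the classes
    inv <- classify_rescue(1 / p[1], 1 / p[2], 1 / p[3], thr = 0.1, eps = 0)
    expect_equal(inv$rescue_class, unname(swap[fwd$rescue_class]))
    expect_equal(classify_rescue(p[1], p[2], p[3], thr = 1e6, eps = 0)$rescue_class,
                 "none")
  }
})

test_that("group proportions are the count-weighted mean of sample proportions", {
  sim <- simulate_cohort(sim_config(n_genes = 30, cells_per_sample = 50), seed = 5)
  pr <- cell_proportions(sim$expr)
  ps <- pr$per_sample
  for (grp in colnames(pr$group)) {
    sub <- ps[ps$group == grp, ]
    n_by_sample <- tapply(sub$n, sub$sample, sum)
    for (ent in rownames(pr$group)) {
      w <- n_by_sample[as.character(unique(sub$sample))]
      p_s <- sub$proportion[match(paste(unique(sub$sample), ent),
                                  paste(sub$sample, sub$entity))]
      expect_equal(unname(pr$group[ent, grp]),
                   unname(sum(w * p_s) / sum(w)), tolerance = 1e-12)
    }
  }
})

test_that("abundance test matches the Welch formula and degenerate rules", {
  props <- list(per_sample = data.frame(
    sample = rep(c("a1", "a2", "a3", "b1", "b2", "b3"), each = 1),
    group = rep(c("DS", "DFUNH"), each = 3),
    entity = "A", n = 10,
    proportion = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)))
  p <- abundance_test(props, "A", c("DS", "DFUNH"))
  expect_equal(p, t.test(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))$p.value)
  expect_equal(p, 0.02131164, tolerance = 1e-6)  # t = -3.674, df = 4
  # identical constant vectors in both groups -> p = 1
  props$per_sample$proportion <- rep(0.25, 6)
  expect_equal(abundance_test(props, "A", c("DS", "DFUNH")), 1)
  # fewer than two samples -> undefined, not an error
  props$per_sample <- props$per_sample[-(1:2), ]
  expect_true(is.na(abundance_test(props, "A", c("DS", "DFUNH"))))
})

test_that("abundance test p-values are uniform under the null", {
  ps <- vapply(1:20, function(s) {
    sim <- simulate_cohort(sim_config(n_genes = 25, cells_per_sample = 60,
                                      n_cell_types = 4, markers_per_type = 0),
                           seed = 1000 + s)
    pr <- cell_proportions(sim$expr)
    abundance_test(pr, "CT1", c("DS", "DFUNH"))
  }, numeric(1))
  expect_gt(mean(ps), 0.2)           # not systematically small
  expect_lte(sum(ps < 0.05), 4)      # ~1 expected under uniformity
})

test_that("phenotype ratios track planted composition reversals", {
  # M1/M2-style ratio: numerator type shrinks then recovers
  props <- matrix(c(0.2, 0.1, 0.3, 0.2, 0.2, 0.2, rep(0.6 / 6, 18)), byrow = TRUE,
                  nrow = 8, dimnames = list(paste0("CT", 1:8), c("DS", "DFUNH", "DFUH")))
  props <- apply(props, 2, function(c) c / sum(c))
  sim <- simulate_cohort(sim_config(n_genes = 25, cells_per_sample = 400,
                                    proportions = props), seed = 3)
  rt <- phenotype_ratio(sim$expr, "CT1", "CT2")
  expect_true(rt[["DFUNH"]] < rt[["DS"]] && rt[["DFUH"]] > rt[["DFUNH"]])
  # direct counts and undefined flag
  counts <- Matrix::Matrix(matrix(1, 1, 5,
                                  dimnames = list("g1", sprintf("c%d", 1:5))),
                           sparse = TRUE)
  meta <- data.frame(cell_id = colnames(counts), sample_id = "s1",
                     group = rep(c("DS", "DFUNH"), c(3, 2)), tissue = "skin",
                     cell_type = c("M1", "M1", "M2", "M1", "M1"),
                     stringsAsFactors = FALSE)
  x <- labeled_expression(counts, meta)
  expect_equal(unname(phenotype_ratio(x, "M1", "M2")["DS"]), 2)
  expect_true(is.na(phenotype_ratio(x, "M1", "M2")[["DFUNH"]]))
})

test_that("rescue_celltypes flags the planted shifted type", {
  props <- fixture_dominant_props(c(0.20, 0.10, 0.18))
  sim <- simulate_cohort(sim_config(n_genes = 30, proportions = props), seed = 1)
  rc <- rescue_celltypes(cell_proportions(sim$expr))
  row <- rc[rc$entity == "CT1", ]
  expect_equal(row$rescue_class, "rescue_up")
  expect_lt(row$l1, -0.1)
  expect_gt(row$l2, 0.1)
})
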