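test_that("profile enumeration counts follow (2c+1)^(T-1)", {
  expect_equal(nrow(make_profiles(3, 1)$values), 9L)
  expect_equal(make_profiles(4, 2, m = 50)$n_candidates, 125L)
  for (T in 3:5) for (c in 1:2) {
    p <- make_profiles(T, c, m = 1e6)
    expect_equal(nrow(p$steps), (2 * c + 1)^(T - 1))
    # values are cumulative sums prefixed with 0
    expect_true(all(p$values[, 1] == 0))
    expect_equal(t(apply(cbind(0, p$steps), 1, cumsum)), p$values,
                 ignore_attr = TRUE)
  }
})

test_that("greedy selection keeps the flat profile and is deterministic", {
  p1 <- make_profiles(4, 2, m = 20)
  expect_equal(nrow(p1$values), 20L)
  expect_true(length(p1$flat_id) == 1 &&
                all(p1$steps[p1$flat_id, ] == 0))
  p2 <- make_profiles(4, 2, m = 20)
  expect_identical(p1$steps, p2$steps)
})

test_that("gene assignment matches the hand-computed correlation example", {
  prof <- make_profiles(3, 1)
  tsr <- trend_series(matrix(c(1.0, 0.2, 1.1), 1,
                             dimnames = list("g1", NULL)), c("t1", "t2", "t3"))
  a <- assign_genes(tsr, prof)
  idx <- which(apply(prof$steps, 1, function(s) all(s == c(-1, 1))))
  expect_equal(a$assignment$profile_id, idx)
  # hand Pearson of translated series (0, -0.8, 0.1) against (0, -1, 0)
  expect_equal(a$assignment$r, cor(c(0, -0.8, 0.1), c(0, -1, 0)),
               tolerance = 1e-12)
  expect_gt(a$assignment$r, 0.99)
})

test_that("constant series go to the flat profile", {
  prof <- make_profiles(3, 1)
  tsr <- trend_series(matrix(5, 1, 3, dimnames = list("g1", NULL)),
                      c("a", "b", "c"))
  a <- assign_genes(tsr, prof)
  expect_equal(a$assignment$profile_id, prof$flat_id)
})

test_that("assignment is invariant to constant shifts and positive scaling", {
  prof <- make_profiles(4, 1)
  set.seed(23)
  V <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("g%02d", 1:10), NULL))
  tp <- paste0("t", 1:4)
  base <- assign_genes(trend_series(V, tp), prof)$assignment$profile_id
  shifted <- assign_genes(trend_series(V + 7, tp), prof)$assignment$profile_id
  scaled <- assign_genes(trend_series(V * 3.5, tp), prof)$assignment$profile_id
  expect_identical(base, shifted)
  expect_identical(base, scaled)
})

test_that("trend classification follows the interior-extremum rule", {
  expect_equal(classify_trend(c(0, 1, 0)), "rescue_down")    # steps (+1, -1)
  expect_equal(classify_trend(c(0, -1, 0)), "rescue_up")     # steps (-1, +1)
  expect_equal(classify_trend(c(0, 1, 2, 0)), "rescue_down") # steps (+1, +1, -2)
  expect_equal(classify_trend(c(0, 1, 2)), "other")          # monotone
  expect_equal(classify_trend(c(0, 0, 0)), "other")          # flat
  expect_equal(classify_trend(c(0, 2, 1, 3)), "other")       # extrema at endpoints
  expect_equal(classify_trend(c(0, -1, -2, -1)), "rescue_up")  # interior minimum
  swap <- c(rescue_up = "rescue_down", rescue_down = "rescue_up", other = "other")
  for (i in 1:20) {
    v <- c(0, cumsum(sample(-1:1, 3, replace = TRUE)))
    # time reversal keeps the class; negation swaps it
    expect_equal(classify_trend(rev(v)), classify_trend(v))
    expect_equal(classify_trend(-v), unname(swap[classify_trend(v)]))
  }
})

test_that("profile significance flags a concentrated profile and not parity", {
  prof <- make_profiles(3, 1)
  # all genes follow (-1, +1): observed ~ n, expected ~ n/9
  set.seed(5)
  V <- t(replicate(100, c(0, -1, 0) + rnorm(3, 0, 0.05)))
  rownames(V) <- sprintf("g%03d", 1:100)
  tsr <- trend_series(V, paste0("t", 1:3))
  sig <- profile_significance(assign_genes(tsr, prof), tsr)
  idx <- which(apply(prof$steps, 1, function(s) all(s == c(-1, 1))))
  expect_lt(sig$profile_stats$p[idx], 1e-6)
  expect_true(sig$profile_stats$significant[idx])
  # observed equal to expected is not significant
  other <- setdiff(seq_len(9), idx)
  expect_true(all(!sig$profile_stats$significant[other] |
                    sig$profile_stats$observed[other] >
                      100 * sig$profile_stats$expected_frac[other]))
})

test_that("planted trend genes at sigma 0.1 are assigned correctly >= 95%", {
  st <- simulate_trend_series(seed = 1)
  prof <- make_profiles(3, 1)
  a <- assign_genes(st$series, prof)
  idx_up <- which(apply(prof$steps, 1, function(s) all(s == c(-1, 1))))
  planted <- st$manifest$gene[st$manifest$steps == "-1,1"]
  acc <- mean(a$assignment$profile_id[match(planted, a$assignment$gene)] == idx_up)
  expect_gte(acc, 0.95)
})

test_that("cross-dataset intersection follows the stated set algebra", {
  sc <- list(rescue_up = c("A", "B", "C"), rescue_down = character())
  bulk <- list(rescue_up = c("B", "C", "D"), rescue_down = character())
  acute <- list(rescue_up = "C", rescue_down = character())
  res <- intersect_rescue(sc, bulk, acute)
  expect_setequal(res$common_up, c("B", "C"))
  expect_equal(res$unique_up, "B")
  # empty acute set leaves unique equal to common
  res2 <- intersect_rescue(sc, bulk)
  expect_setequal(res2$unique_up, res2$common_up)
  # symbols are harmonized by uppercasing
  res3 <- intersect_rescue(list(rescue_up = "col1a1", rescue_down = character()),
                           list(rescue_up = "COL1A1", rescue_down = character()))
  expect_equal(res3$common_up, "COL1A1")
})
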