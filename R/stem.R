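# all permutations of 1..n, deterministic lexicographic order
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# 1 - Pearson distance between profile value vectors; a flat profile is at
# distance 1 from every non-flat profile and 0 from another flat one
.profile_dist <- function(V) {
  s <- apply(V, 1, stats::sd)
  D <- matrix(1, nrow(V), nrow(V))
  ok <- s > 0
  if (sum(ok) > 1) D[ok, ok] <- 1 - stats::cor(t(V[ok, , drop = FALSE]))
  D[!ok, !ok] <- 0
  diag(D) <- 0
  D
}

#' Enumerate (and select) model profiles for short time series
#'
#' A model profile is a piecewise-linear template of integer unit changes
#' per timestep, each in `[-c, c]`; its value vector is the cumulative sum
#' prefixed with 0. All `(2c+1)^(T-1)` candidates are enumerated in
#' deterministic order; when more than `m` exist, `m` representatives are
#' selected greedily to maximize the minimum pairwise distance (1 minus the
#' Pearson correlation of value vectors), always retaining the flat
#' profile.
#'
#' @param T number of timepoints (>= 2)
#' @param c maximum unit change per step (>= 1)
#' @param m maximum number of profiles kept (default 50)
#' @return list of class `wr_profiles`: `steps` and `values` matrices (one
#'   row per profile), `flat_id`, `n_candidates`, `T`, `c`
#' @export
make_profiles <- function(T, c = 2, m = 50) {
  stopifnot(T >= 2, c >= 1, m >= 1)
  grid <- as.matrix(expand.grid(rep(list(seq(-c, c)), T - 1)))
  dimnames(grid) <- NULL
  values <- if (T == 2) cbind(0, grid) else cbind(0, t(apply(grid, 1, cumsum)))
  n_cand <- nrow(grid)
  flat <- which(rowSums(abs(grid)) == 0)
  if (n_cand > m) {
    D <- .profile_dist(values)
    selected <- flat
    while (length(selected) < m) {
      cand <- setdiff(seq_len(n_cand), selected)
      mind <- apply(D[cand, selected, drop = FALSE], 1, min)
      selected <- c(selected, cand[which.max(mind)])
    }
    selected <- sort(selected)
    grid <- grid[selected, , drop = FALSE]
    values <- values[selected, , drop = FALSE]
    flat <- which(rowSums(abs(grid)) == 0)
  }
  structure(list(steps = grid, values = values, flat_id = flat,
                 n_candidates = n_cand, T = T, c = c),
            class = "wr_profiles")
}

#' Assign gene series to their best-matching model profile
#'
#' Each gene's series is translated to start at 0 (first value
#' subtracted) and assigned to the profile whose value vector has maximal
#' Pearson correlation with it; constant series go to the flat profile;
#' ties break to the lowest profile id. Assignment is invariant to adding a
#' constant to a series and to positive scaling.
#'
#' @param series a `TrendSeries`
#' @param profiles a [make_profiles()] result with the same `T`
#' @return list of class `wr_assignment`: `assignment` (data.frame `gene`,
#'   `profile_id`, `r`) and `profiles`
#' @export
assign_genes <- function(series, profiles) {
  V <- series$values
  if (ncol(V) != profiles$T) stop("series and profiles disagree on T")
  G <- V - V[, 1]
  P <- profiles$values
  Pc <- P - rowMeans(P)
  Pn <- sqrt(rowSums(Pc^2))
  Ps <- Pc / ifelse(Pn > 0, Pn, 1)          # flat rows become zero vectors
  Gc <- G - rowMeans(G)
  Gn <- sqrt(rowSums(Gc^2))
  const_gene <- Gn == 0
  Gs <- Gc / ifelse(Gn > 0, Gn, 1)
  R <- Gs %*% t(Ps)
  R[, Pn == 0] <- -Inf                       # never match the flat template by r
  best <- max.col(R, ties.method = "first")
  r <- R[cbind(seq_len(nrow(R)), best)]
  best[const_gene] <- profiles$flat_id
  r[const_gene] <- NA_real_
  structure(list(assignment = data.frame(gene = rownames(V),
                                         profile_id = best, r = r,
                                         stringsAsFactors = FALSE),
                 profiles = profiles),
            class = "wr_assignment")
}

#' Classify a profile value vector as a rescue trend
#'
#' `rescue_down` when the trajectory rises to a strictly interior maximum
#' and falls afterwards (net change before the extremum > 0, after it < 0);
#' `rescue_up` is the mirror around the minimum. Trajectories whose
#' extremum sits at an endpoint, flat profiles, and balanced ambiguous
#' shapes are `other`.
#'
#' @param values profile value vector (length >= 3, starting at 0)
#' @return one of `"rescue_up"`, `"rescue_down"`, `"other"`
#' @export
classify_trend <- function(values) {
  T <- length(values)
  stopifnot(T >= 3)
  imax <- which.max(values); imin <- which.min(values)
  down_ok <- imax > 1 && imax < T &&
    (values[imax] - values[1]) > 0 && (values[T] - values[imax]) < 0
  up_ok <- imin > 1 && imin < T &&
    (values[imin] - values[1]) < 0 && (values[T] - values[imin]) > 0
  if (down_ok && up_ok) {
    amp_down <- values[imax] - min(values[1], values[T])
    amp_up <- max(values[1], values[T]) - values[imin]
    if (amp_down > amp_up) return("rescue_down")
    if (amp_up > amp_down) return("rescue_up")
    return("other")
  }
  if (down_ok) return("rescue_down")
  if (up_ok) return("rescue_up")
  "other"
}

#' Permutation significance of profile memberships
#'
#' The expected membership fraction of each profile is the mean fraction of
#' genes assigned to it when the series' timepoint columns are permuted
#' (all `T!` orders when `T! <= n_perm`, else `n_perm` sampled orders). The
#' p-value is the binomial upper tail `P(X >= observed)` at that fraction,
#' Bonferroni-corrected over the number of profiles.
#'
#' @param assignment a [assign_genes()] result
#' @param series the `TrendSeries` it was computed on
#' @param n_perm permutation budget (default: all orders for `T <= 5`,
#'   i.e. 120)
#' @param alpha significance level after Bonferroni (default 0.05)
#' @param seed seed used only when orders are sampled
#' @return `assignment` with a `profile_stats` data.frame added: per
#'   profile `profile_id`, `observed`, `expected_frac`, `p`, `p_adj`,
#'   `significant`, `trend_class`
#' @export
profile_significance <- function(assignment, series, n_perm = 120,
                                 alpha = 0.05, seed = 1L) {
  profiles <- assignment$profiles
  T <- profiles$T
  k <- nrow(profiles$values)
  n_genes <- nrow(assignment$assignment)
  nf <- factorial(T)
  perms <- if (nf <= n_perm) {
    .permutations(T)
  } else {
    withr::with_seed(stage_seed(seed, "profile_significance"),
                     t(replicate(n_perm, sample.int(T))))
  }
  counts <- matrix(0, nrow(perms), k)
  for (i in seq_len(nrow(perms))) {
    perm_series <- trend_series(series$values[, perms[i, ], drop = FALSE],
                                series$timepoints)
    a <- assign_genes(perm_series, profiles)
    tab <- tabulate(a$assignment$profile_id, nbins = k)
    counts[i, ] <- tab
  }
  expected_frac <- colMeans(counts) / n_genes
  observed <- tabulate(assignment$assignment$profile_id, nbins = k)
  p <- vapply(seq_len(k), function(j) {
    if (expected_frac[j] >= 1) return(1)
    pbinom(observed[j] - 1, n_genes, expected_frac[j], lower.tail = FALSE)
  }, numeric(1))
  p_adj <- pmin(1, p * k)
  trend_class <- apply(profiles$values, 1, classify_trend)
  assignment$profile_stats <- data.frame(
    profile_id = seq_len(k), observed = observed,
    expected_frac = expected_frac, p = p, p_adj = p_adj,
    significant = p_adj < alpha, trend_class = trend_class,
    stringsAsFactors = FALSE)
  assignment
}

#' Rescue-trend gene sets from a significance-annotated assignment
#'
#' Genes assigned to Bonferroni-significant profiles classified
#' `rescue_up` (down-then-up) or `rescue_down` (up-then-down).
#'
#' @param assignment a [profile_significance()] result
#' @return list with `rescue_up` and `rescue_down` gene vectors
#' @export
rescue_trend_genes <- function(assignment) {
  st <- assignment$profile_stats
  if (is.null(st)) stop("run profile_significance first")
  a <- assignment$assignment
  pick <- function(cls) {
    ids <- st$profile_id[st$significant & st$trend_class == cls]
    sort(unique(a$gene[a$profile_id %in% ids]))
  }
  list(rescue_up = pick("rescue_up"), rescue_down = pick("rescue_down"))
}

.as_rescue_sets <- function(x) {
  if (inherits(x, "wr_deg_sets"))
    return(list(rescue_up = x$genes$rescue_up, rescue_down = x$genes$rescue_down))
  if (inherits(x, "wr_assignment")) return(rescue_trend_genes(x))
  stopifnot(is.list(x), all(c("rescue_up", "rescue_down") %in% names(x)))
  x
}

#' Intersect single-cell, bulk and acute rescue gene sets
#'
#' Direction-matched set logic of the cross-dataset screen: `common` =
#' single-cell rescue genes also showing a significant bulk rescue trend;
#' `unique` = common genes minus genes with the same reversing trend during
#' acute (non-diabetic) wound healing, leaving changes specific to the
#' diabetic healing process. Gene symbols are uppercased before matching.
#'
#' @param sc_sets single-cell rescue sets: a `wr_deg_sets` or a list with
#'   `rescue_up` / `rescue_down`
#' @param bulk bulk trend sets: a significance-annotated `wr_assignment`
#'   or such a list
#' @param acute acute-wound trend sets, same forms as `bulk`
#' @return list: `common_up`, `common_down`, `unique_up`, `unique_down`
#' @export
intersect_rescue <- function(sc_sets, bulk, acute = list(rescue_up = character(),
                                                         rescue_down = character())) {
  sc <- lapply(.as_rescue_sets(sc_sets), toupper)
  bk <- lapply(.as_rescue_sets(bulk), toupper)
  ac <- lapply(.as_rescue_sets(acute), toupper)
  common_up <- intersect(sc$rescue_up, bk$rescue_up)
  common_down <- intersect(sc$rescue_down, bk$rescue_down)
  list(common_up = common_up, common_down = common_down,
       unique_up = setdiff(common_up, ac$rescue_up),
       unique_down = setdiff(common_down, ac$rescue_down))
}
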