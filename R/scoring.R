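#' Control-binned module score per cell
#'
#' Activity of a gene set in each cell: genes are binned into `nbin`
#' near-equal-size bins by their average normalized expression across
#' cells; for each member gene, `nctrl` control genes are drawn with
#' replacement from its bin, and the score is the mean member expression
#' minus the mean control expression, per cell. A set of genes behaving
#' like their expression-matched background therefore scores ~0.
#'
#' @param x a `LabeledExpression` with a norm layer
#' @param gene_set character vector of member genes
#' @param nbin number of average-expression bins (default 24)
#' @param nctrl control genes drawn per member gene (default 100)
#' @param seed integer seed for the control draw
#' @return named numeric vector of per-cell scores
#' @export
module_score <- function(x, gene_set, nbin = 24, nctrl = 100, seed = 1L) {
  if (is.null(x$norm)) stop("norm layer required; run normalize_counts first")
  members <- intersect(gene_set, rownames(x$norm))
  if (!length(members)) stop("no member gene present in the matrix")
  if (nrow(x$norm) < nbin) stop("fewer genes than bins")
  avg <- Matrix::rowMeans(x$norm)
  bin <- ceiling(rank(avg, ties.method = "first") / (length(avg) / nbin))
  bin <- pmin(pmax(bin, 1), nbin)
  names(bin) <- rownames(x$norm)
  ctrl <- withr::with_seed(stage_seed(seed, "module_score"), {
    unlist(lapply(members, function(g) {
      pool <- names(bin)[bin == bin[[g]]]
      sample(pool, nctrl, replace = TRUE)
    }))
  })
  member_mean <- Matrix::colMeans(x$norm[members, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(x$norm[ctrl, , drop = FALSE])
  setNames(as.numeric(member_mean - ctrl_mean), colnames(x$norm))
}

# signed enrichment score from hit positions in a ranked list
.gsea_es <- function(pos, w, N) {
  k <- length(pos)
  if (k == 0 || k >= N) stop("set must hit between 1 and N-1 genes")
  sw <- sum(w)
  w <- if (sw > 0) w / sw else rep(1 / k, k)
  cw <- cumsum(w)
  miss <- 1 / (N - k)
  j <- seq_len(k)
  top <- cw - (pos - j) * miss              # running sum just after each hit
  bottom <- c(0, cw[-k]) - (pos - 1 - (j - 1)) * miss  # just before each hit
  cand <- c(top, bottom)
  cand[which.max(abs(cand))]
}

#' Preranked gene set enrichment of one set
#'
#' Kolmogorov-Smirnov-style running sum over the metric-ranked gene list:
#' hits add `|metric|^p` (normalized over hits), misses subtract
#' `1/(N - n_set)`; the enrichment score (ES) is the extreme deviation.
#' The null is gene-label permutation (random sets of the same size);
#' `NES = ES / mean |null ES of the same sign|` and the p-value is the
#' one-sided permutation tail with add-one smoothing.
#'
#' @param ranked named numeric vector: gene-level metric (e.g. DE log2FC);
#'   sorted internally by decreasing value
#' @param gene_set character vector of member genes (must intersect
#'   `names(ranked)` but not cover it)
#' @param weight_p hit-weight exponent (default 1)
#' @param nperm permutations (default 1000)
#' @param seed integer seed
#' @return one-row data.frame: `n_genes`, `n_hits`, `es`, `nes`, `p`
#' @export
gsea_preranked <- function(ranked, gene_set, weight_p = 1, nperm = 1000,
                           seed = 1L) {
  if (any(!is.finite(ranked))) stop("metric values must be finite")
  ord <- order(ranked, decreasing = TRUE)
  metric <- ranked[ord]
  N <- length(metric)
  hit <- names(metric) %in% gene_set
  k <- sum(hit)
  if (k == 0) stop("gene set does not intersect the ranked list")
  if (k == N) stop("gene set covers the whole ranked list")
  pos <- which(hit)
  es <- .gsea_es(pos, abs(metric[pos])^weight_p, N)
  null_es <- withr::with_seed(stage_seed(seed, "gsea"), {
    vapply(seq_len(nperm), function(i) {
      np <- sort(sample.int(N, k))
      .gsea_es(np, abs(metric[np])^weight_p, N)
    }, numeric(1))
  })
  same <- null_es[sign(null_es) == sign(es)]
  if (length(same)) {
    nes <- es / mean(abs(same))
    p <- (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1)
  } else {
    nes <- sign(es) * Inf
    p <- 1 / (nperm + 1)
  }
  data.frame(n_genes = N, n_hits = k, es = es, nes = nes, p = p)
}

#' GSEA over a collection of gene sets with BH correction
#'
#' Runs [gsea_preranked()] on each set, adjusts p-values across sets with
#' Benjamini-Hochberg, and flags significance at `adjp` with `|NES| >=
#' nes_min`.
#'
#' @inheritParams gsea_preranked
#' @param gene_sets named list of gene vectors (e.g. from [read_gmt()])
#' @param adjp adjusted-p threshold (default 0.05)
#' @param nes_min minimum |NES| (default 1)
#' @return data.frame with one row per set: `set`, `n_hits`, `es`, `nes`,
#'   `p`, `p_adj`, `significant`
#' @export
gsea_table <- function(ranked, gene_sets, weight_p = 1, nperm = 1000,
                       seed = 1L, adjp = 0.05, nes_min = 1.0) {
  rows <- lapply(names(gene_sets), function(nm) {
    r <- gsea_preranked(ranked, gene_sets[[nm]], weight_p = weight_p,
                        nperm = nperm, seed = stage_seed(seed, nm))
    cbind(set = nm, r[, c("n_hits", "es", "nes", "p")])
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < adjp & abs(out$nes) >= nes_min
  rownames(out) <- NULL
  out
}

#' Rank genes for single-cell GSEA from a DE contrast
#'
#' Filters a [de_contrast()] result of one cell type (or pooled) at
#' adjusted p < `adjp` and average |log2FC| > `logfc_min`, then returns the
#' log2FC-ranked metric vector used as GSEA input.
#'
#' @param de a [de_contrast()] data.frame (one cell type)
#' @param adjp adjusted-p filter (default 0.05)
#' @param logfc_min |log2FC| filter (default 0.5)
#' @return named numeric vector sorted by decreasing log2FC
#' @export
gsea_rank_from_de <- function(de, adjp = 0.05, logfc_min = 0.5) {
  keep <- de$p_adj < adjp & abs(de$log2fc) > logfc_min
  v <- setNames(de$log2fc[keep], de$gene[keep])
  sort(v, decreasing = TRUE)
}
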