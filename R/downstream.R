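#' Transcriptional-diversity differentiation score
#'
#' A rank-normalized per-cell differentiation statistic driven by the
#' number of expressed genes (higher = less differentiated): per cell,
#' count genes with count > 0; correlate each gene's normalized expression
#' with those gene counts across cells; average the normalized expression
#' of the `n_top` most positively correlated genes per cell (the gene
#' counts signature, GCS); rank-normalize the GCS to `[0, 1]`. Subcluster
#' medians give a differentiation ordering (descending score = earlier /
#' less differentiated).
#'
#' @param x a `LabeledExpression` with a norm layer (>= 50 cells
#'   recommended); set `subcluster` in meta for the ordering output
#' @param n_top number of signature genes (default 200)
#' @return list of class `wr_cytotrace`: `score` (named per-cell vector in
#'   `[0, 1]`), `gcs`, `signature_genes`, `degenerate`, and when
#'   subclusters are present `subcluster_median` and `order` (descending
#'   median score)
#' @export
cytotrace_score <- function(x, n_top = 200) {
  if (is.null(x$norm)) stop("norm layer required; run normalize_counts first")
  n_cells <- ncol(x$counts)
  gene_counts <- as.numeric(Matrix::colSums(x$counts > 0))
  if (sd(gene_counts) == 0) {
    score <- setNames(rep(0.5, n_cells), colnames(x$counts))
    res <- list(score = score, gcs = score, signature_genes = character(),
                degenerate = TRUE)
  } else {
    M <- as.matrix(x$norm)
    gsd <- apply(M, 1, sd)
    r <- rep(-Inf, nrow(M))
    r[gsd > 0] <- as.numeric(cor(t(M[gsd > 0, , drop = FALSE]), gene_counts))
    top <- order(r, decreasing = TRUE)[seq_len(min(n_top, sum(gsd > 0)))]
    gcs <- colMeans(M[top, , drop = FALSE])
    score <- (rank(gcs, ties.method = "average") - 1) / (n_cells - 1)
    res <- list(score = setNames(score, colnames(x$counts)),
                gcs = setNames(gcs, colnames(x$counts)),
                signature_genes = rownames(M)[top], degenerate = FALSE)
  }
  if ("subcluster" %in% colnames(x$meta) && !anyNA(x$meta$subcluster)) {
    med <- tapply(res$score[x$meta$cell_id], x$meta$subcluster, median)
    res$subcluster_median <- med
    res$order <- names(sort(med, decreasing = TRUE))
  }
  structure(res, class = "wr_cytotrace")
}

#' ROC area under the curve for one feature
#'
#' AUC via the Mann-Whitney identity `U / (n_pos * n_neg)` with ties
#' counted 1/2, equal to the trapezoidal area under the empirical ROC
#' curve. With `direction = "auto"` (the default) the class with the
#' higher mean value is treated as positive, so the reported AUC is
#' >= 0.5 and `flipped` records the orientation; `direction = "forward"`
#' scores the labels as given (label flipping then maps AUC to 1 - AUC).
#'
#' @param values numeric feature values, one per sample
#' @param labels binary class labels (logical, 0/1, or two-level factor;
#'   `TRUE`/1/second level = positive)
#' @param direction `"auto"` or `"forward"`
#' @param auc_thr biomarker call threshold (default 0.7)
#' @return list of class `wr_roc`: `auc`, `n_pos`, `n_neg`, `flipped`,
#'   `biomarker` (`auc > auc_thr`)
#' @export
roc_auc <- function(values, labels, direction = c("auto", "forward"),
                    auc_thr = 0.7) {
  direction <- match.arg(direction)
  if (is.factor(labels) || is.character(labels)) {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) != 2) stop("labels must have exactly two classes")
    pos <- as.character(labels) == lev[[2]]
  } else {
    pos <- as.logical(labels)
  }
  stopifnot(length(values) == length(pos), !anyNA(values), !anyNA(pos))
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(values, ties.method = "average")
  U <- sum(r[pos]) - n_pos * (n_pos + 1) / 2
  auc <- U / (n_pos * n_neg)
  flipped <- FALSE
  if (direction == "auto" && auc < 0.5) {
    auc <- 1 - auc
    flipped <- TRUE
  }
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg, flipped = flipped,
                 biomarker = auc > auc_thr),
            class = "wr_roc")
}

#' AUC screen over a feature matrix
#'
#' [roc_auc()] for each row of a feature x sample matrix against one
#' binary label vector; the biomarker flag uses `auc_thr`.
#'
#' @param features numeric matrix (features x samples, rownames = feature
#'   ids)
#' @param labels binary labels, one per column
#' @inheritParams roc_auc
#' @return data.frame: `feature`, `auc`, `n_pos`, `n_neg`, `flipped`,
#'   `biomarker`
#' @export
roc_screen <- function(features, labels, direction = "auto", auc_thr = 0.7) {
  rows <- lapply(rownames(features), function(f) {
    r <- roc_auc(features[f, ], labels, direction = direction, auc_thr = auc_thr)
    data.frame(feature = f, auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg,
               flipped = r$flipped, biomarker = r$biomarker,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
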