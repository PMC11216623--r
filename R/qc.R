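#' Cell-level quality-control thresholds
#'
#' Defaults follow standard droplet scRNA-seq practice for wound/skin
#' tissue: 500-10,000 genes detected and 1,000-100,000 UMIs (inclusive
#' ranges), mitochondrial UMI fraction < 30% and hemoglobin UMI fraction
#' < 5% (strict, matching the "< 30%" / "< 5%" notation). Mitochondrial
#' genes are recognized by id prefix, hemoglobin genes by an explicit list;
#' both are configurable because gene naming differs across references.
#'
#' @param min_genes,max_genes inclusive bounds on genes detected (count > 0)
#' @param min_umi,max_umi inclusive bounds on total UMIs per cell
#' @param max_mito_frac strict upper bound on mitochondrial UMI fraction
#' @param max_hemo_frac strict upper bound on hemoglobin UMI fraction
#' @param mito_prefix gene-id prefix marking mitochondrial genes
#' @param hemo_genes explicit hemoglobin gene list
#' @return list of class `wr_qc_thresholds`
#' @export
qc_thresholds <- function(min_genes = 500, max_genes = 10000,
                          min_umi = 1000, max_umi = 100000,
                          max_mito_frac = 0.30, max_hemo_frac = 0.05,
                          mito_prefix = "MT-",
                          hemo_genes = c("HBB", "HBA1", "HBA2")) {
  if (min_genes >= max_genes) stop("min_genes must be < max_genes")
  if (min_umi >= max_umi) stop("min_umi must be < max_umi")
  for (f in c(max_mito_frac, max_hemo_frac))
    if (f <= 0 || f > 1) stop("fraction bounds must lie in (0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_umi = min_umi, max_umi = max_umi,
                 max_mito_frac = max_mito_frac, max_hemo_frac = max_hemo_frac,
                 mito_prefix = mito_prefix, hemo_genes = hemo_genes),
            class = "wr_qc_thresholds")
}

#' Per-cell QC statistics
#'
#' @param x a `LabeledExpression`
#' @param thr a [qc_thresholds()] object (for the mito/hemo gene lists)
#' @return data.frame with `cell_id`, `n_genes`, `n_umi`, `mito_frac`,
#'   `hemo_frac`
#' @export
qc_stats <- function(x, thr = qc_thresholds()) {
  counts <- x$counts
  n_umi <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), thr$mito_prefix)
  hemo <- rownames(counts) %in% thr$hemo_genes
  mito_umi <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
  hemo_umi <- if (any(hemo)) Matrix::colSums(counts[hemo, , drop = FALSE]) else 0
  data.frame(cell_id = colnames(counts),
             n_genes = as.numeric(n_genes), n_umi = as.numeric(n_umi),
             mito_frac = ifelse(n_umi > 0, mito_umi / n_umi, 0),
             hemo_frac = ifelse(n_umi > 0, hemo_umi / n_umi, 0),
             stringsAsFactors = FALSE)
}

#' Filter cells on QC thresholds
#'
#' A cell is retained iff genes detected and total UMIs fall inside their
#' inclusive ranges AND both contamination fractions fall strictly below
#' their bounds. Filtering is idempotent.
#'
#' @param x a `LabeledExpression` with raw counts
#' @param thr a [qc_thresholds()] object
#' @return list with `expr` (filtered `LabeledExpression`) and `report`
#'   (`n_input`, `n_retained`, per-criterion removal counts; a cell may
#'   violate several criteria).
#' @export
filter_cells <- function(x, thr = qc_thresholds()) {
  st <- qc_stats(x, thr)
  fail_genes_low <- st$n_genes < thr$min_genes
  fail_genes_high <- st$n_genes > thr$max_genes
  fail_umi_low <- st$n_umi < thr$min_umi
  fail_umi_high <- st$n_umi > thr$max_umi
  fail_mito <- st$mito_frac >= thr$max_mito_frac
  fail_hemo <- st$hemo_frac >= thr$max_hemo_frac
  keep <- !(fail_genes_low | fail_genes_high | fail_umi_low |
              fail_umi_high | fail_mito | fail_hemo)
  if (!any(keep)) stop("all cells removed by QC filtering")
  report <- list(n_input = nrow(st), n_retained = sum(keep),
                 n_removed = sum(!keep),
                 removed = list(genes_low = sum(fail_genes_low),
                                genes_high = sum(fail_genes_high),
                                umi_low = sum(fail_umi_low),
                                umi_high = sum(fail_umi_high),
                                mito = sum(fail_mito),
                                hemo = sum(fail_hemo)))
  list(expr = subset_cells(x, which(keep)), report = report)
}

#' Log-normalize UMI counts
#'
#' Adds a `norm` layer with `norm[g, c] = ln(1 + counts[g, c] * scale /
#' total_umi[c])` (log-CPX with the conventional scale 1e4). Counts are
#' left untouched; the transform is invariant to per-cell count scaling and
#' monotone within a cell.
#'
#' @param x a `LabeledExpression`
#' @param scale pseudo library size (default 1e4)
#' @return `x` with the `norm` layer set
#' @export
normalize_counts <- function(x, scale = 1e4) {
  counts <- x$counts
  n_umi <- Matrix::colSums(counts)
  if (any(n_umi == 0))
    stop("zero-UMI cell(s) present: ",
         paste(head(colnames(counts)[n_umi == 0], 5), collapse = ", "),
         " (run filter_cells first)")
  norm <- counts
  percol <- rep.int(scale / n_umi, diff(counts@p))
  norm@x <- log1p(counts@x * percol)
  x$norm <- norm
  validate_labeled_expression(x)
}
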