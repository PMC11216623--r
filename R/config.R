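#' Pipeline run configuration
#'
#' Bundles the thresholds used across the pipeline stages with their
#' published defaults: cell-composition |log2FC| cutoff 0.1, differential
#' expression |log2FC| 0.25 at BH-adjusted p < 0.01, ligand-receptor logFC
#' 0.2, trend-profile significance 0.05, GSEA adjusted p 0.05 with
#' |NES| >= 1, and AUC 0.7 for biomarker calls. All randomized stages take
#' `seed`; per-stage streams are derived deterministically with
#' [stage_seed()] so partial re-runs reproduce.
#'
#' @param prop_log2fc_thr composition rescue |log2FC| threshold
#' @param de_logfc_thr DE |log2FC| threshold
#' @param de_adjp_thr DE BH-adjusted p threshold
#' @param lr_logfc_thr ligand/receptor logFC threshold
#' @param stem list: `c` (max unit change per step), `m` (max profiles),
#'   `n_perm`, `alpha`
#' @param gsea list: `nperm`, `adjp`, `nes_min`
#' @param auc_thr biomarker AUC threshold
#' @param seed master integer seed
#' @return list of class `wr_config`
#' @export
run_config <- function(prop_log2fc_thr = 0.1,
                       de_logfc_thr = 0.25,
                       de_adjp_thr = 0.01,
                       lr_logfc_thr = 0.2,
                       stem = list(c = 2, m = 50, n_perm = 120, alpha = 0.05),
                       gsea = list(nperm = 1000, adjp = 0.05, nes_min = 1.0),
                       auc_thr = 0.7,
                       seed = 1L) {
  thr <- c(prop_log2fc_thr, de_logfc_thr, de_adjp_thr, lr_logfc_thr, auc_thr)
  if (any(thr <= 0)) stop("all thresholds must be strictly positive")
  for (a in c(stem$alpha, gsea$adjp))
    if (a <= 0 || a >= 1) stop("alpha values must lie in (0, 1)")
  structure(list(prop_log2fc_thr = prop_log2fc_thr,
                 de_logfc_thr = de_logfc_thr, de_adjp_thr = de_adjp_thr,
                 lr_logfc_thr = lr_logfc_thr, stem = stem, gsea = gsea,
                 auc_thr = auc_thr, seed = as.integer(seed)),
            class = "wr_config")
}

#' Derive a per-stage seed from the master seed
#'
#' Deterministic and stage-name keyed, so re-running a single stage draws
#' the same random stream as a full run. Arithmetic stays within exact
#' double-precision integers; the result is a valid 32-bit seed.
#'
#' @param seed master integer seed
#' @param stage stage name, e.g. `"simulate"`, `"module_score"`
#' @return integer in `[0, 2^31 - 1)`
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 48271 + h) %% 2147483629)
}
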