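# Tukey trimean (Q1 + 2*Q2 + Q3) / 4, a robust location estimate
.trimean <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  (q[1] + 2 * q[2] + q[3]) / 4
}

.geomean <- function(v) exp(mean(log(v)))

# per-cell-type robust expression of the genes in `genes`, for one group
.type_expression <- function(x, group, genes, method = "trimean") {
  cells_by_type <- split(x$meta$cell_id[x$meta$group == group],
                         x$meta$cell_type[x$meta$group == group])
  fun <- if (method == "trimean") .trimean else mean
  sapply(cells_by_type, function(cells) {
    M <- as.matrix(x$norm[genes, cells, drop = FALSE])
    apply(M, 1, fun)
  }, simplify = "array")
}

#' Ligand-receptor communication probabilities for one clinical group
#'
#' For every (sender type, receiver type, LR pair): `L` is the Tukey
#' trimean of ligand expression in the sender (geometric mean over
#' multiple ligand genes), `R` the geometric mean over receptor subunits
#' of their trimeans in the receiver, and the communication probability
#' follows the Hill mass-action form `prob = L*R / (Kh + L*R)` with
#' `Kh = 0.5`. The probability is 0 whenever either side's expression is 0
#' and is monotone nondecreasing in `L` and `R`, bounded in `[0, 1)`.
#'
#' @param x a `LabeledExpression` with a norm layer
#' @param group clinical group to score
#' @param lr_db LR database (see [read_lr_database()]); pairs with genes
#'   absent from the matrix are skipped with a warning
#' @param kh Hill half-saturation constant (default 0.5)
#' @param method `"trimean"` (default) or `"mean"` expression summary
#' @return data.frame of edges: `sender`, `receiver`, `pair_name`,
#'   `pathway`, `L`, `R`, `prob`
#' @export
comm_prob <- function(x, group, lr_db, kh = 0.5, method = c("trimean", "mean")) {
  method <- match.arg(method)
  if (is.null(x$norm)) stop("norm layer required; run normalize_counts first")
  present <- vapply(seq_len(nrow(lr_db)), function(i)
    all(c(lr_db$ligand_genes[[i]], lr_db$receptor_genes[[i]]) %in% rownames(x$norm)),
    logical(1))
  if (any(!present))
    warning("skipping LR pairs with genes absent from the matrix: ",
            paste(lr_db$pair_name[!present], collapse = ", "))
  db <- lr_db[present, , drop = FALSE]
  if (!nrow(db)) stop("no LR pair has all genes in the matrix")
  genes <- unique(unlist(c(db$ligand_genes, db$receptor_genes)))
  E <- .type_expression(x, group, genes, method)   # gene x cell_type
  if (is.null(dim(E))) E <- matrix(E, nrow = 1, dimnames = list(genes, NULL))
  types <- colnames(E)
  edges <- expand.grid(sender = types, receiver = types, i = seq_len(nrow(db)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  L <- vapply(seq_len(nrow(edges)), function(r) {
    .geomean(E[db$ligand_genes[[edges$i[r]]], edges$sender[r]])
  }, numeric(1))
  R <- vapply(seq_len(nrow(edges)), function(r) {
    .geomean(E[db$receptor_genes[[edges$i[r]]], edges$receiver[r]])
  }, numeric(1))
  data.frame(sender = edges$sender, receiver = edges$receiver,
             pair_name = db$pair_name[edges$i], pathway = db$pathway[edges$i],
             L = L, R = R, prob = L * R / (kh + L * R),
             stringsAsFactors = FALSE)
}

#' Hill communication probability
#'
#' The mass-action form `L*R / (Kh + L*R)` used by [comm_prob()], exposed
#' for direct evaluation.
#'
#' @param L,R ligand and receptor expression summaries (>= 0)
#' @param kh half-saturation constant (default 0.5)
#' @export
hill_prob <- function(L, R, kh = 0.5) {
  stopifnot(all(L >= 0), all(R >= 0), kh > 0)
  L * R / (kh + L * R)
}

#' Differential classification of LR edges between two groups
#'
#' For each edge, the ligand log2FC is computed within the sender cell
#' type and the receptor log2FC within the receiver cell type (the
#' within-type Wilcoxon DE fold change, second group vs first). The edge
#' is `up` when ligand and receptor log2FC are both `>= thr`, `down` when
#' both `<= -thr` (boundaries inclusive), else `none`. Multi-gene ligands
#' and multi-subunit receptors use the mean log2FC of their genes. Edges
#' whose sender or receiver type fails the eligibility rule (fewer than
#' `min_cells` cells in either group) are not classified.
#'
#' @param x a `LabeledExpression` with a norm layer
#' @param lr_db LR database
#' @param group_a,group_b first and second group of the contrast (log2FC
#'   sign is b minus a, e.g. `group_a = "DS"`, `group_b = "DFUNH"` for the
#'   unhealing contrast)
#' @param thr logFC threshold (default 0.2)
#' @param min_cells eligibility threshold per cell type (default 3)
#' @return data.frame: `sender`, `receiver`, `pair_name`, `pathway`,
#'   `ligand_log2fc`, `receptor_log2fc`, `diff_class`
#' @export
diff_lr <- function(x, lr_db, group_a, group_b, thr = 0.2, min_cells = 3) {
  types <- eligible_cell_types(x, group_a, group_b, min_cells)
  if (!length(types)) stop("no eligible cell types for ", group_a, " vs ", group_b)
  present <- vapply(seq_len(nrow(lr_db)), function(i)
    all(c(lr_db$ligand_genes[[i]], lr_db$receptor_genes[[i]]) %in% rownames(x$norm)),
    logical(1))
  db <- lr_db[present, , drop = FALSE]
  genes <- unique(unlist(c(db$ligand_genes, db$receptor_genes)))
  xs <- x
  xs$counts <- xs$counts[genes, , drop = FALSE]
  xs$norm <- xs$norm[genes, , drop = FALSE]
  fc <- sapply(types, function(ct) {
    de <- wilcoxon_de(xs, ct, group_b, group_a)   # sign: b minus a
    setNames(de$log2fc, de$gene)
  })
  edges <- expand.grid(sender = types, receiver = types, i = seq_len(nrow(db)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lfc <- vapply(seq_len(nrow(edges)), function(r)
    mean(fc[db$ligand_genes[[edges$i[r]]], edges$sender[r]]), numeric(1))
  rfc <- vapply(seq_len(nrow(edges)), function(r)
    mean(fc[db$receptor_genes[[edges$i[r]]], edges$receiver[r]]), numeric(1))
  cls <- ifelse(lfc >= thr & rfc >= thr, "up",
                ifelse(lfc <= -thr & rfc <= -thr, "down", "none"))
  data.frame(sender = edges$sender, receiver = edges$receiver,
             pair_name = db$pair_name[edges$i], pathway = db$pathway[edges$i],
             ligand_log2fc = lfc, receptor_log2fc = rfc, diff_class = cls,
             stringsAsFactors = FALSE)
}

#' Rescue classification of LR edges across the two contrasts
#'
#' Joins the unhealing (DFUNH vs DS) and healing (DFUH vs DFUNH)
#' differential edge classifications on (sender, receiver, pair):
#' `rescue_up` edges are down in the unhealing contrast and up in the
#' healing contrast; `rescue_down` is the mirror.
#'
#' @param diff_unhealing,diff_healing [diff_lr()] results on the same edge
#'   universe
#' @return joined data.frame with `unhealing_class`, `healing_class`,
#'   `rescue_class`
#' @export
rescue_lr <- function(diff_unhealing, diff_healing) {
  key_u <- paste(diff_unhealing$sender, diff_unhealing$receiver,
                 diff_unhealing$pair_name, sep = "\r")
  key_h <- paste(diff_healing$sender, diff_healing$receiver,
                 diff_healing$pair_name, sep = "\r")
  m <- match(key_u, key_h)
  keep <- !is.na(m)
  out <- diff_unhealing[keep, c("sender", "receiver", "pair_name", "pathway")]
  out$unhealing_class <- diff_unhealing$diff_class[keep]
  out$healing_class <- diff_healing$diff_class[m[keep]]
  out$rescue_class <- ifelse(
    out$unhealing_class == "down" & out$healing_class == "up", "rescue_up",
    ifelse(out$unhealing_class == "up" & out$healing_class == "down",
           "rescue_down", "none"))
  rownames(out) <- NULL
  out
}

#' Pathway-level summary of communication edges
#'
#' Sums edge probabilities and counts edges per pathway label, the simple
#' network-level summary of signaling strength per pathway.
#'
#' @param edges a [comm_prob()] result
#' @return data.frame: `pathway`, `n_edges`, `total_prob`
#' @export
pathway_summary <- function(edges) {
  agg <- aggregate(edges$prob, by = list(pathway = edges$pathway),
                   FUN = function(v) c(n = length(v), s = sum(v)))
  data.frame(pathway = agg$pathway, n_edges = agg$x[, "n"],
             total_prob = agg$x[, "s"], stringsAsFactors = FALSE)
}
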