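#' Cell-type (or subcluster) proportions per group and per sample
#'
#' Group-level proportions are cell counts of each entity divided by the
#' total cells of the group; per-sample proportions are computed the same
#' way within each sample. An entity absent from a group gets proportion 0.
#'
#' @param x a `LabeledExpression`
#' @param by `"cell_type"` or `"subcluster"` (the same machinery serves
#'   fibroblast subclusters by switching the level)
#' @return list of class `wr_proportions` with `group` (entity x group
#'   matrix, columns summing to 1), `per_sample` (long data.frame `sample`,
#'   `group`, `entity`, `n`, `proportion`) and `by`
#' @export
cell_proportions <- function(x, by = c("cell_type", "subcluster")) {
  by <- match.arg(by)
  if (!by %in% colnames(x$meta)) stop("meta has no column '", by, "'")
  labels <- as.character(x$meta[[by]])
  if (anyNA(labels)) stop("missing ", by, " labels")
  groups <- intersect(WR_GROUPS, unique(as.character(x$meta$group)))
  entities <- sort(unique(labels))
  gm <- sapply(groups, function(grp) {
    ing <- x$meta$group == grp
    if (!any(ing)) stop("group ", grp, " has zero cells")
    tab <- table(factor(labels[ing], levels = entities))
    as.numeric(tab) / sum(ing)
  })
  rownames(gm) <- entities
  per_sample <- do.call(rbind, lapply(unique(x$meta$sample_id), function(s) {
    ins <- x$meta$sample_id == s
    tab <- table(factor(labels[ins], levels = entities))
    data.frame(sample = s, group = x$meta$group[ins][1], entity = entities,
               n = as.numeric(tab), proportion = as.numeric(tab) / sum(ins),
               stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  structure(list(group = gm, per_sample = per_sample, by = by),
            class = "wr_proportions")
}

#' Classify a three-state proportion trajectory as rescued
#'
#' Computes `l1 = log2((p_nh + eps) / (p_ds + eps))` (unhealing contrast)
#' and `l2 = log2((p_h + eps) / (p_nh + eps))` (healing contrast). The
#' entity is `rescue_up` when it drops in non-healing ulcers and recovers
#' in healing ulcers (`l1 < -thr` and `l2 > thr`), `rescue_down` in the
#' mirrored case, otherwise `none`. A zero proportion with `eps = 0` makes
#' the record degenerate (non-finite log ratio) and never a rescue call.
#'
#' @param p_ds,p_nh,p_h proportions in the DS, DFUNH and DFUH groups
#' @param thr |log2FC| threshold (default 0.1)
#' @param eps pseudo-proportion added before the log ratio; pass
#'   `0.5 / n_cells_in_group` for a Haldane-style correction of absent
#'   entities
#' @return list: `l1`, `l2`, `rescue_class`, `degenerate`
#' @export
classify_rescue <- function(p_ds, p_nh, p_h, thr = 0.1, eps = 0) {
  if (any(c(p_ds, p_nh, p_h) < 0)) stop("proportions must be >= 0")
  stopifnot(thr > 0, eps >= 0)
  l1 <- log2((p_nh + eps) / (p_ds + eps))
  l2 <- log2((p_h + eps) / (p_nh + eps))
  degenerate <- !is.finite(l1) || !is.finite(l2)
  cls <- "none"
  if (!degenerate) {
    if (l1 < -thr && l2 > thr) cls <- "rescue_up"
    if (l1 > thr && l2 < -thr) cls <- "rescue_down"
  }
  list(l1 = l1, l2 = l2, rescue_class = cls, degenerate = degenerate)
}

#' Rescue classification of every entity in a proportion table
#'
#' Applies [classify_rescue()] to each entity's group proportions, using a
#' Haldane-style pseudo-proportion `0.5 / min(group cell count)` for
#' entities absent from some group, and attaches Welch t-test p-values for
#' both contrasts from the per-sample proportions.
#'
#' @param props a [cell_proportions()] result
#' @param thr |log2FC| threshold (default 0.1)
#' @param eps pseudo-proportion; `NULL` (default) derives the Haldane-style
#'   value from the group sizes
#' @return data.frame: `entity`, `p_ds`, `p_nh`, `p_h`, `l1`, `l2`,
#'   `rescue_class`, `degenerate`, `p_unhealing`, `p_healing`
#' @export
rescue_celltypes <- function(props, thr = 0.1, eps = NULL) {
  gm <- props$group
  if (!all(WR_GROUPS %in% colnames(gm)))
    stop("all three groups are required for rescue classification")
  if (is.null(eps)) {
    group_n <- tapply(props$per_sample$n,
                      props$per_sample$group, sum)[WR_GROUPS]
    eps <- if (any(gm == 0)) 0.5 / min(group_n) else 0
  }
  rows <- lapply(rownames(gm), function(ent) {
    cl <- classify_rescue(gm[ent, "DS"], gm[ent, "DFUNH"], gm[ent, "DFUH"],
                          thr = thr, eps = eps)
    data.frame(entity = ent, p_ds = gm[ent, "DS"], p_nh = gm[ent, "DFUNH"],
               p_h = gm[ent, "DFUH"], l1 = cl$l1, l2 = cl$l2,
               rescue_class = cl$rescue_class, degenerate = cl$degenerate,
               p_unhealing = abundance_test(props, ent, c("DS", "DFUNH")),
               p_healing = abundance_test(props, ent, c("DFUNH", "DFUH")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch t-test on per-sample proportions of one entity
#'
#' Tests whether the entity's per-sample proportions differ between two
#' clinical groups (unequal-variance two-sample t-test, two-sided).
#' Degenerate inputs follow explicit rules: identical constant vectors in
#' both groups give p = 1; fewer than 2 samples in either group gives `NA`
#' (undefined, not an error).
#'
#' @param props a [cell_proportions()] result
#' @param entity entity label
#' @param groups character vector of two group labels
#' @return two-sided p-value (or 1 / `NA` per the degenerate rules)
#' @export
abundance_test <- function(props, entity, groups) {
  stopifnot(length(groups) == 2)
  ps <- props$per_sample
  a <- ps$proportion[ps$entity == entity & ps$group == groups[[1]]]
  b <- ps$proportion[ps$entity == entity & ps$group == groups[[2]]]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (var(a) == 0 && var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  t.test(a, b, var.equal = FALSE)$p.value
}

#' Cell-count ratio between two phenotypes, per group
#'
#' For phenotype pairs such as pro- vs anti-inflammatory macrophages
#' (M1/M2) or classical vs non-classical monocytes (CD14/CD16): the ratio
#' of cell counts of the numerator type to the denominator type in each
#' clinical group. A zero denominator flags the ratio undefined (`NA`).
#'
#' @param x a `LabeledExpression`
#' @param numerator_type,denominator_type cell-type labels
#' @return named numeric vector over the groups present (NA where
#'   undefined)
#' @export
phenotype_ratio <- function(x, numerator_type, denominator_type) {
  groups <- intersect(WR_GROUPS, unique(as.character(x$meta$group)))
  vapply(groups, function(grp) {
    ing <- x$meta$group == grp
    num <- sum(x$meta$cell_type[ing] == numerator_type)
    den <- sum(x$meta$cell_type[ing] == denominator_type)
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
}
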