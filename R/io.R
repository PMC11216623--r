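#' @importFrom methods as is new
#' @importFrom stats aggregate cor median p.adjust pbinom pnorm pwilcox
#'   quantile rlnorm rnbinom rnorm sd setNames t.test var
#' @importFrom utils combn head read.delim write.table read.csv write.csv
NULL

#' Clinical group vocabulary
#'
#' The three clinical states of the analysis, ordered along the healing
#' pseudo-trajectory: diabetic skin without ulcer (DS), non-healing diabetic
#' foot ulcer (DFUNH), healing diabetic foot ulcer (DFUH).
#' @export
WR_GROUPS <- c("DS", "DFUNH", "DFUH")

#' Tissue vocabulary
#' @export
WR_TISSUES <- c("skin", "blood")

#' Construct a labeled expression object
#'
#' The substrate of every pipeline stage: a sparse gene x cell UMI count
#' matrix together with per-cell metadata (sample, clinical group, tissue,
#' cell type, optional subcluster) and, after [normalize_counts()], a
#' natural-log normalized layer of identical shape.
#'
#' @param counts gene x cell matrix of non-negative integer UMI counts;
#'   coerced to `dgCMatrix`. Must carry unique row (gene) and column (cell)
#'   names.
#' @param meta data.frame with one row per cell and columns `cell_id`,
#'   `sample_id`, `group` (one of `WR_GROUPS`), `tissue` (one of
#'   `WR_TISSUES`), `cell_type`, and optionally `subcluster`.
#' @param norm optional gene x cell matrix of normalized expression, same
#'   dimnames as `counts`, all values >= 0.
#' @return object of class `LabeledExpression`: a list with elements
#'   `counts`, `meta`, `norm` (possibly `NULL`).
#' @export
labeled_expression <- function(counts, meta, norm = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  obj <- structure(list(counts = counts, meta = meta, norm = norm),
                   class = "LabeledExpression")
  validate_labeled_expression(obj)
  obj
}

#' Validate a labeled expression object
#'
#' Checks dimension/metadata consistency, the closed group and tissue
#' vocabularies, count non-negativity, and the shape of the normalized
#' layer. Called by every constructor and reader; analysis stages may assume
#' a validated object.
#'
#' @param x a `LabeledExpression`
#' @return `x`, invisibly; errors describe every offending cell or label.
#' @export
validate_labeled_expression <- function(x) {
  stopifnot(inherits(x, "LabeledExpression"))
  counts <- x$counts
  meta <- x$meta
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell ids in counts")
  req <- c("cell_id", "sample_id", "group", "tissue", "cell_type")
  miss_col <- setdiff(req, colnames(meta))
  if (length(miss_col))
    stop("meta is missing required columns: ", paste(miss_col, collapse = ", "))
  if (anyDuplicated(meta$cell_id))
    stop("duplicate cell_id in meta")
  absent <- setdiff(colnames(counts), meta$cell_id)
  if (length(absent))
    stop("cells in matrix absent from meta: ",
         paste(head(absent, 10), collapse = ", "),
         if (length(absent) > 10) sprintf(" (and %d more)", length(absent) - 10) else "")
  extra <- setdiff(meta$cell_id, colnames(counts))
  if (length(extra))
    stop("meta rows for cells absent from matrix: ",
         paste(head(extra, 10), collapse = ", "))
  bad_grp <- setdiff(unique(as.character(meta$group)), WR_GROUPS)
  if (length(bad_grp))
    stop("unknown group labels: ", paste(bad_grp, collapse = ", "),
         " (allowed: ", paste(WR_GROUPS, collapse = ", "), ")")
  bad_tis <- setdiff(unique(as.character(meta$tissue)), WR_TISSUES)
  if (length(bad_tis))
    stop("unknown tissue labels: ", paste(bad_tis, collapse = ", "))
  if (any(counts@x < 0)) stop("negative counts")
  if (!is.null(x$norm)) {
    if (!identical(dim(x$norm), dim(counts)))
      stop("norm layer shape differs from counts")
    if (any(x$norm@x < 0)) stop("negative values in norm layer")
  }
  invisible(x)
}

#' @export
print.LabeledExpression <- function(x, ...) {
  cat(sprintf("LabeledExpression: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  groups:    ", paste(sprintf("%s=%d", names(table(x$meta$group)),
                                     table(x$meta$group)), collapse = "  "), "\n")
  cat("  cell types:", length(unique(x$meta$cell_type)),
      " | samples:", length(unique(x$meta$sample_id)),
      " | norm layer:", if (is.null(x$norm)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.LabeledExpression <- function(x) dim(x$counts)

#' Subset cells of a labeled expression object
#'
#' @param x a `LabeledExpression`
#' @param cells character vector of cell ids, or logical/integer index over
#'   columns.
#' @return `LabeledExpression` restricted to the selected cells (meta rows
#'   reordered to match the matrix).
#' @export
subset_cells <- function(x, cells) {
  if (is.character(cells)) {
    missing <- setdiff(cells, colnames(x$counts))
    if (length(missing)) stop("unknown cell ids: ", paste(head(missing, 5), collapse = ", "))
    keep <- cells
  } else {
    keep <- colnames(x$counts)[cells]
  }
  meta <- x$meta[match(keep, x$meta$cell_id), , drop = FALSE]
  rownames(meta) <- NULL
  labeled_expression(x$counts[, keep, drop = FALSE], meta,
                     norm = if (is.null(x$norm)) NULL else x$norm[, keep, drop = FALSE])
}

#' Read a labeled expression bundle
#'
#' Reads the on-disk interchange bundle: a Matrix Market coordinate file
#' with genes as rows and cells as columns, sidecar gene/cell id lists (one
#' id per line), and a cell metadata TSV with columns `cell_id`,
#' `sample_id`, `group`, `tissue`, `cell_type` and optional `subcluster`.
#'
#' @param matrix_path path to the `.mtx` file
#' @param genes_path path to the gene id list
#' @param cells_path path to the cell id list
#' @param meta_path path to the metadata TSV
#' @return validated `LabeledExpression` (no norm layer)
#' @export
read_labeled_expression <- function(matrix_path, genes_path, cells_path, meta_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop(sprintf("matrix is %d x %d but sidecars list %d genes and %d cells",
                 nrow(m), ncol(m), length(genes), length(cells)))
  dimnames(m) <- list(genes, cells)
  meta <- read.delim(meta_path, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = "character")
  labeled_expression(m, meta)
}

#' Write a labeled expression bundle
#'
#' Inverse of [read_labeled_expression()]; writes `matrix.mtx`,
#' `genes.tsv`, `cells.tsv`, `meta.tsv` under `dir`. The norm layer is not
#' serialized (it is recomputed deterministically by [normalize_counts()]).
#'
#' @param x a `LabeledExpression`
#' @param dir output directory, created if needed
#' @return `dir`, invisibly
#' @export
write_labeled_expression <- function(x, dir) {
  validate_labeled_expression(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "cells.tsv"))
  write.table(x$meta, file.path(dir, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: tab-separated lines `name<TAB>description<TAB>gene...`
#' @return named list of character vectors (duplicate members deduplicated,
#'   order of first appearance preserved).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d fields; need name, description and >= 1 gene",
                   i, length(fields)))
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("GMT line %d defines an empty set", i))
    sets[[fields[[1]]]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors
#' @param path output file
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ligand-receptor pair database
#'
#' CSV with columns `pair_name`, `pathway`, `ligand_genes`,
#' `receptor_genes`; the gene columns are `;`-separated lists (multi-subunit
#' receptors keep their order). Gene symbols are uppercased.
#'
#' @param path CSV file
#' @return data.frame with list-columns `ligand_genes` and
#'   `receptor_genes`.
#' @export
read_lr_database <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("pair_name", "pathway", "ligand_genes", "receptor_genes")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("LR database missing columns: ", paste(miss, collapse = ", "))
  split_genes <- function(v, what) {
    lapply(seq_along(v), function(i) {
      g <- toupper(trimws(strsplit(v[[i]], ";", fixed = TRUE)[[1]]))
      g <- g[nzchar(g)]
      if (!length(g))
        stop(sprintf("LR pair '%s' has an empty %s field", df$pair_name[[i]], what))
      g
    })
  }
  data.frame(pair_name = df$pair_name, pathway = df$pathway,
             ligand_genes = I(split_genes(df$ligand_genes, "ligand")),
             receptor_genes = I(split_genes(df$receptor_genes, "receptor")),
             stringsAsFactors = FALSE)
}

#' Write a ligand-receptor pair database
#' @param db data.frame as returned by [read_lr_database()]
#' @param path output CSV
#' @export
write_lr_database <- function(db, path) {
  out <- data.frame(
    pair_name = db$pair_name, pathway = db$pathway,
    ligand_genes = vapply(db$ligand_genes, paste, character(1), collapse = ";"),
    receptor_genes = vapply(db$receptor_genes, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a truth manifest to JSON
#' @param manifest list as produced by [simulate_cohort()]
#' @param path output JSON file
#' @export
write_truth_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a truth manifest from JSON
#' @param path JSON file written by [write_truth_manifest()]
#' @export
read_truth_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
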