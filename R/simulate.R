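#' Simulation configuration for the three-group cohort
#'
#' The generator emulates the structure the rescue analysis assumes:
#' negative-binomial UMI counts with log-normal baseline abundances,
#' cell-type-specific marker genes, group-dependent cell-type proportions,
#' genes whose expression drops in non-healing ulcers and recovers in
#' healing ulcers (and the reverse), and ligand-receptor pairs whose
#' sender/receiver expression reverses. Defaults: 3 samples per clinical
#' group, 200 cells per sample, 1,000 genes, 8 cell types with 5 marker
#' genes each (5x baseline in their type), NB dispersion 0.5, ~2,000
#' expected UMIs per cell with log-normal(0, 0.3) library-size variation.
#'
#' Gene ids are assigned in order of decreasing baseline abundance
#' (`G0001` is the most abundant gene), so fixtures can plant effects at a
#' known expression level; marker genes occupy the most abundant ids, as
#' real marker transcripts tend to do.
#'
#' @param n_samples integer vector of samples per group, named or ordered
#'   DS, DFUNH, DFUH
#' @param cells_per_sample cells drawn per sample
#' @param n_genes gene universe size
#' @param n_cell_types number of cell types (labeled `CT1`, `CT2`, ...)
#' @param markers_per_type marker genes per cell type
#' @param marker_factor fold-increase of a marker gene in its own type
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2)
#' @param baseline_meanlog,baseline_sdlog log-normal baseline abundance
#' @param target_umi expected UMIs per cell before library-size variation
#' @param libsize_sdlog sdlog of the per-cell library-size factor
#' @param tissue tissue label stamped on all cells
#' @param proportions optional cell-type x group matrix of proportions
#'   (columns DS, DFUNH, DFUH, each summing to 1); default uniform
#' @param rescue_genes optional data.frame with columns `gene`,
#'   `cell_type` (a type label or `"all"`), `direction` (`"up"` = drops in
#'   DFUNH then recovers in DFUH), `fc_unhealing`, `fc_healing`
#'   (multiplicative fold changes applied DS->DFUNH and DFUNH->DFUH)
#' @param lr_reversals optional data.frame with columns `pair_name`,
#'   `sender`, `receiver`, `direction`, `fc_unhealing`, `fc_healing`; needs
#'   `lr_db`
#' @param lr_db ligand-receptor database (see [read_lr_database()]) whose
#'   gene symbols exist in the simulated gene universe
#' @param gene_ids optional explicit gene id vector of length `n_genes`
#' @return list of class `wr_sim_config`
#' @export
sim_config <- function(n_samples = c(DS = 3, DFUNH = 3, DFUH = 3),
                       cells_per_sample = 200,
                       n_genes = 1000,
                       n_cell_types = 8,
                       markers_per_type = 5,
                       marker_factor = 5,
                       dispersion = 0.5,
                       baseline_meanlog = 0,
                       baseline_sdlog = 1,
                       target_umi = 2000,
                       libsize_sdlog = 0.3,
                       tissue = "skin",
                       proportions = NULL,
                       rescue_genes = NULL,
                       lr_reversals = NULL,
                       lr_db = NULL,
                       gene_ids = NULL) {
  if (is.null(names(n_samples))) names(n_samples) <- WR_GROUPS
  stopifnot(setequal(names(n_samples), WR_GROUPS), dispersion > 0)
  cell_types <- paste0("CT", seq_len(n_cell_types))
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes, !anyDuplicated(gene_ids))
  if (is.null(proportions)) {
    proportions <- matrix(1 / n_cell_types, n_cell_types, 3,
                          dimnames = list(cell_types, WR_GROUPS))
  }
  stopifnot(identical(sort(rownames(proportions)), sort(cell_types)),
            all(colnames(proportions) %in% WR_GROUPS))
  if (any(abs(colSums(proportions) - 1) > 1e-9))
    stop("each group's cell-type proportions must sum to 1")
  if (!is.null(rescue_genes)) {
    bad <- setdiff(rescue_genes$gene, gene_ids)
    if (length(bad)) stop("planted genes not in universe: ", paste(head(bad, 5), collapse = ", "))
    bad_ct <- setdiff(setdiff(rescue_genes$cell_type, "all"), cell_types)
    if (length(bad_ct)) stop("planted cell types not in universe: ", paste(bad_ct, collapse = ", "))
    if (any(c(rescue_genes$fc_unhealing, rescue_genes$fc_healing) <= 0))
      stop("fold changes must be > 0")
  }
  if (!is.null(lr_reversals)) {
    if (is.null(lr_db)) stop("lr_reversals requires lr_db")
    bad_pair <- setdiff(lr_reversals$pair_name, lr_db$pair_name)
    if (length(bad_pair)) stop("planted LR pairs not in lr_db: ", paste(bad_pair, collapse = ", "))
    lr_genes <- unique(unlist(c(lr_db$ligand_genes, lr_db$receptor_genes)))
    bad_g <- setdiff(lr_genes, gene_ids)
    if (length(bad_g)) stop("LR database genes not in universe: ", paste(head(bad_g, 5), collapse = ", "))
    bad_ct <- setdiff(c(lr_reversals$sender, lr_reversals$receiver), cell_types)
    if (length(bad_ct)) stop("planted LR cell types not in universe: ", paste(bad_ct, collapse = ", "))
  }
  structure(list(n_samples = n_samples[WR_GROUPS], cells_per_sample = cells_per_sample,
                 n_genes = n_genes, gene_ids = gene_ids, cell_types = cell_types,
                 markers_per_type = markers_per_type, marker_factor = marker_factor,
                 dispersion = dispersion, baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, target_umi = target_umi,
                 libsize_sdlog = libsize_sdlog, tissue = tissue,
                 proportions = proportions, rescue_genes = rescue_genes,
                 lr_reversals = lr_reversals, lr_db = lr_db),
            class = "wr_sim_config")
}

# expand planted LR reversals into per-gene effects restricted to
# sender (ligand genes) and receiver (receptor subunits) cell types
.expand_lr_effects <- function(cfg) {
  if (is.null(cfg$lr_reversals)) return(NULL)
  out <- list()
  for (i in seq_len(nrow(cfg$lr_reversals))) {
    rv <- cfg$lr_reversals[i, ]
    row <- cfg$lr_db[cfg$lr_db$pair_name == rv$pair_name, ]
    for (g in row$ligand_genes[[1]])
      out[[length(out) + 1]] <- data.frame(gene = g, cell_type = rv$sender,
                                           direction = rv$direction,
                                           fc_unhealing = rv$fc_unhealing,
                                           fc_healing = rv$fc_healing)
    for (g in row$receptor_genes[[1]])
      out[[length(out) + 1]] <- data.frame(gene = g, cell_type = rv$receiver,
                                           direction = rv$direction,
                                           fc_unhealing = rv$fc_unhealing,
                                           fc_healing = rv$fc_healing)
  }
  unique(do.call(rbind, out))
}

#' Simulate a labeled three-group single-cell cohort
#'
#' Draws cell-type labels per sample from the group's proportion vector and
#' UMI counts from `NegativeBinomial(mean = baseline x marker factor x
#' group factor x library factor, dispersion)`. Planted effects (rescue
#' genes, LR reversals, proportion shifts) are recorded in a truth manifest
#' for parameter-recovery tests. Identical `(config, seed)` yields
#' identical output.
#'
#' @param config a [sim_config()]
#' @param seed integer seed
#' @return list with `expr` (a `LabeledExpression`) and `manifest` (planted
#'   effects, NB parameters, seed)
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  withr::with_seed(stage_seed(seed, "simulate"), {
    baseline <- rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
    baseline <- sort(baseline, decreasing = TRUE)   # ids ordered by abundance
    baseline <- baseline / sum(baseline) * cfg$target_umi
    names(baseline) <- cfg$gene_ids

    marker_map <- NULL
    n_marked <- cfg$markers_per_type * length(cfg$cell_types)
    if (cfg$markers_per_type > 0 && n_marked <= cfg$n_genes) {
      marker_map <- data.frame(
        gene = cfg$gene_ids[seq_len(n_marked)],
        cell_type = rep(cfg$cell_types, each = cfg$markers_per_type),
        stringsAsFactors = FALSE)
    }

    effects <- cfg$rescue_genes
    lr_eff <- .expand_lr_effects(cfg)
    all_eff <- rbind(effects, lr_eff)

    meta_l <- list(); count_l <- list()
    for (grp in WR_GROUPS) {
      for (s in seq_len(cfg$n_samples[[grp]])) {
        sample_id <- sprintf("%s_s%d", grp, s)
        types <- sample(rownames(cfg$proportions), cfg$cells_per_sample,
                        replace = TRUE, prob = cfg$proportions[, grp])
        lib <- rlnorm(cfg$cells_per_sample, 0, cfg$libsize_sdlog)
        mu <- matrix(baseline, cfg$n_genes, cfg$cells_per_sample)
        if (!is.null(marker_map)) {
          for (ct in unique(types)) {
            mg <- marker_map$gene[marker_map$cell_type == ct]
            if (length(mg))
              mu[match(mg, cfg$gene_ids), types == ct] <-
                mu[match(mg, cfg$gene_ids), types == ct] * cfg$marker_factor
          }
        }
        if (!is.null(all_eff) && grp != "DS") {
          for (k in seq_len(nrow(all_eff))) {
            e <- all_eff[k, ]
            fac <- if (grp == "DFUNH") e$fc_unhealing else e$fc_unhealing * e$fc_healing
            cols <- if (e$cell_type == "all") rep(TRUE, length(types)) else types == e$cell_type
            if (any(cols)) {
              gi <- match(e$gene, cfg$gene_ids)
              mu[gi, cols] <- mu[gi, cols] * fac
            }
          }
        }
        mu <- sweep(mu, 2, lib, "*")
        cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                      cfg$n_genes, cfg$cells_per_sample)
        colnames(cnt) <- sprintf("%s_c%04d", sample_id, seq_len(cfg$cells_per_sample))
        rownames(cnt) <- cfg$gene_ids
        count_l[[sample_id]] <- cnt
        meta_l[[sample_id]] <- data.frame(
          cell_id = colnames(cnt), sample_id = sample_id, group = grp,
          tissue = cfg$tissue, cell_type = types, stringsAsFactors = FALSE)
      }
    }
    counts <- Matrix::Matrix(do.call(cbind, count_l), sparse = TRUE)
    meta <- do.call(rbind, meta_l)
    rownames(meta) <- NULL
    expr <- labeled_expression(counts, meta)
    manifest <- list(
      seed = as.integer(seed),
      planted_rescue_genes = effects,
      planted_lr_reversals = cfg$lr_reversals,
      planted_lr_gene_effects = lr_eff,
      planted_celltype_shifts = as.data.frame(cfg$proportions),
      marker_genes = marker_map,
      nb_params = list(dispersion = cfg$dispersion,
                       baseline_meanlog = cfg$baseline_meanlog,
                       baseline_sdlog = cfg$baseline_sdlog,
                       target_umi = cfg$target_umi))
    list(expr = expr, manifest = manifest)
  })
}

#' Construct a trend series
#'
#' A gene x timepoint matrix of mean expression with ordered timepoint
#' labels, the input of the profile-clustering stage (at most 8
#' timepoints).
#'
#' @param values numeric gene x timepoint matrix with gene rownames
#' @param timepoints ordered timepoint labels (defaults to colnames)
#' @return object of class `TrendSeries`
#' @export
trend_series <- function(values, timepoints = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(timepoints)) stop("timepoint labels required")
  if (length(timepoints) != ncol(values)) stop("timepoints must match columns")
  if (length(timepoints) > 8) stop("at most 8 timepoints supported")
  if (any(!is.finite(values))) stop("non-finite values in series")
  colnames(values) <- timepoints
  structure(list(values = values, timepoints = timepoints), class = "TrendSeries")
}

#' Group-mean pseudo-bulk series
#'
#' Averages each gene's normalized expression over the cells of each
#' clinical group, yielding the gene x state matrix that the trend stage
#' clusters (the three states are treated as an ordered pseudo time
#' series).
#'
#' @param x a `LabeledExpression` with a norm layer
#' @param order group labels in series order (default DS, DFUNH, DFUH)
#' @return a `TrendSeries`
#' @export
pseudobulk_means <- function(x, order = WR_GROUPS) {
  if (is.null(x$norm)) stop("norm layer required; run normalize_counts first")
  stopifnot(all(order %in% WR_GROUPS))
  cols <- lapply(order, function(grp) {
    idx <- which(x$meta$group == grp)
    if (!length(idx)) stop("no cells in group ", grp)
    Matrix::rowMeans(x$norm[, x$meta$cell_id[idx], drop = FALSE])
  })
  trend_series(do.call(cbind, setNames(cols, order)), order)
}

#' Simulate a short mean-expression trend series
#'
#' Every gene receives a true piecewise-linear profile of unit steps;
#' background genes draw each step from `{-1, 0, +1}` with probabilities
#' `background_probs` (defaults make most transcripts stable, with
#' occasional unit drifts, as in real bulk series), while planted rescue
#' genes get a designated down-then-up (`rescue_up`) or up-then-down
#' (`rescue_down`) pattern. Observed values are the true values plus a
#' per-gene baseline offset and Gaussian noise.
#'
#' @param n_genes gene universe size
#' @param timepoints ordered labels (3 to 8)
#' @param n_rescue_up,n_rescue_down numbers of planted reversing genes
#' @param planted_up,planted_down optional explicit gene ids to plant
#'   (override the counts; useful to overlap planted sets across simulated
#'   datasets)
#' @param noise_sd Gaussian noise standard deviation (default 0.1)
#' @param background_probs sampling probabilities of steps -1, 0, +1 for
#'   background genes
#' @param seed integer seed
#' @param gene_ids optional explicit gene ids
#' @return list with `series` (a `TrendSeries`) and `manifest`
#'   (data.frame `gene`, `steps`, `trend_class` for every gene)
#' @export
simulate_trend_series <- function(n_genes = 1000,
                                  timepoints = c("t1", "t2", "t3"),
                                  n_rescue_up = 200, n_rescue_down = 200,
                                  noise_sd = 0.1,
                                  background_probs = c(0.2, 0.6, 0.2),
                                  seed = 1L, gene_ids = NULL,
                                  planted_up = NULL, planted_down = NULL) {
  T <- length(timepoints)
  stopifnot(T >= 3, n_rescue_up + n_rescue_down <= n_genes)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(planted_up) || !is.null(planted_down)) {
    stopifnot(all(c(planted_up, planted_down) %in% gene_ids),
              !anyDuplicated(c(planted_up, planted_down)))
  }
  withr::with_seed(stage_seed(seed, "trend_series"), {
    steps <- matrix(sample(c(-1L, 0L, 1L), n_genes * (T - 1), replace = TRUE,
                           prob = background_probs),
                    n_genes, T - 1)
    up_pattern <- c(-1L, rep(0L, max(0, T - 3)), 1L)
    down_pattern <- c(1L, rep(0L, max(0, T - 3)), -1L)
    if (T == 4) { up_pattern <- c(-1L, -1L, 1L); down_pattern <- c(1L, 1L, -1L) }
    idx_up <- if (is.null(planted_up)) seq_len(n_rescue_up) else match(planted_up, gene_ids)
    idx_down <- if (is.null(planted_down)) seq_len(n_rescue_down) + n_rescue_up else match(planted_down, gene_ids)
    if (!is.null(planted_up) || !is.null(planted_down)) {
      if (length(intersect(idx_up, idx_down))) stop("planted sets overlap")
    }
    if (length(idx_up)) steps[idx_up, ] <- matrix(up_pattern, length(idx_up), T - 1, byrow = TRUE)
    if (length(idx_down)) steps[idx_down, ] <- matrix(down_pattern, length(idx_down), T - 1, byrow = TRUE)
    true_vals <- cbind(0, t(apply(steps, 1, cumsum)))
    offset <- rnorm(n_genes, 0, 2)
    vals <- true_vals + offset + matrix(rnorm(n_genes * T, 0, noise_sd), n_genes, T)
    rownames(vals) <- gene_ids
    manifest <- data.frame(
      gene = gene_ids,
      steps = apply(steps, 1, paste, collapse = ","),
      trend_class = vapply(seq_len(n_genes), function(i)
        classify_trend(c(0, cumsum(steps[i, ]))), character(1)),
      stringsAsFactors = FALSE)
    list(series = trend_series(vals, timepoints), manifest = manifest)
  })
}

#' Simulate an acute-wound four-timepoint series
#'
#' Emulates the design of an acute wound-healing time course (days 0, 1, 3
#' and 7 post-wounding): a four-point mean-expression series with planted
#' up-then-down and down-then-up genes recorded in the manifest.
#'
#' @inheritParams simulate_trend_series
#' @export
simulate_acute_series <- function(n_genes = 1000,
                                  n_rescue_up = 200, n_rescue_down = 200,
                                  noise_sd = 0.1, seed = 1L,
                                  gene_ids = NULL) {
  simulate_trend_series(n_genes = n_genes,
                        timepoints = c("day0", "day1", "day3", "day7"),
                        n_rescue_up = n_rescue_up, n_rescue_down = n_rescue_down,
                        noise_sd = noise_sd, seed = seed, gene_ids = gene_ids)
}

#' Deterministic QC test fixture
#'
#' Builds a 100-cell counts matrix over a 12,000-gene universe (including
#' mitochondrial `MT-*` and hemoglobin genes) in which exactly
#' `n_violations` cells violate a QC criterion: too few genes (also too few
#' UMIs), too many genes, too many UMIs, mitochondrial fraction >= 30%, or
#' hemoglobin fraction >= 5%. All other cells sit comfortably inside the
#' default thresholds.
#'
#' @param seed integer seed (controls which cell slots are violators and
#'   which genes each cell expresses)
#' @param n_cells total cells (default 100)
#' @param n_violations planted violator cells (default 17)
#' @return list with `expr` (a `LabeledExpression`), `expected_retained`
#'   (cell ids that must survive [filter_cells()]) and `violations`
#'   (data.frame of planted violator cells and their kind)
#' @export
simulate_qc_fixture <- function(seed = 1L, n_cells = 100, n_violations = 17) {
  stopifnot(n_violations <= n_cells)
  n_genes <- 12000
  mito <- sprintf("MT-%d", 1:10)
  hemo <- c("HBB", "HBA1", "HBA2")
  genes <- c(mito, hemo, sprintf("G%05d", seq_len(n_genes - 13)))
  plain <- setdiff(genes, c(mito, hemo))
  kinds <- rep(c("genes_low", "genes_high", "umi_high", "mito", "hemo"),
               length.out = n_violations)
  withr::with_seed(stage_seed(seed, "qc_fixture"), {
    viol_slots <- sort(sample(n_cells, n_violations))
    cell_kind <- rep("pass", n_cells)
    cell_kind[viol_slots] <- sample(kinds)
    ii <- list(); jj <- list(); xx <- list()
    for (c in seq_len(n_cells)) {
      k <- cell_kind[[c]]
      if (k == "pass") {
        g <- sample(plain, 2000); x <- rep(1, 2000)
      } else if (k == "genes_low") {
        g <- sample(plain, 300); x <- rep(1, 300)
      } else if (k == "genes_high") {
        g <- sample(plain, 10500); x <- rep(1, 10500)
      } else if (k == "umi_high") {
        g <- sample(plain, 1500); x <- rep(80, 1500)
      } else if (k == "mito") {
        g <- c(sample(plain, 1990), mito); x <- c(rep(1, 1990), rep(100, 10))
      } else { # hemo
        g <- c(sample(plain, 1997), hemo); x <- c(rep(1, 1997), rep(40, 3))
      }
      ii[[c]] <- match(g, genes); jj[[c]] <- rep(c, length(g)); xx[[c]] <- x
    }
    counts <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                                   dims = c(n_genes, n_cells),
                                   dimnames = list(genes, sprintf("cell%03d", seq_len(n_cells))))
    meta <- data.frame(cell_id = colnames(counts), sample_id = "fix_s1",
                       group = "DS", tissue = "skin", cell_type = "CT1",
                       stringsAsFactors = FALSE)
    list(expr = labeled_expression(counts, meta),
         expected_retained = colnames(counts)[cell_kind == "pass"],
         violations = data.frame(cell_id = colnames(counts)[viol_slots],
                                 kind = cell_kind[viol_slots],
                                 stringsAsFactors = FALSE))
  })
}
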