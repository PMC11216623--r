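# Shared fixture builders; everything is generated in code at test time.

# tiny deterministic 3-gene x 4-cell object spanning two groups
tiny_expr <- function() {
  counts <- Matrix::Matrix(matrix(c(5, 0, 1,
                                    2, 3, 0,
                                    0, 1, 4,
                                    7, 2, 2), nrow = 3),
                           sparse = TRUE)
  dimnames(counts) <- list(c("GA", "GB", "GC"), paste0("c", 1:4))
  meta <- data.frame(cell_id = paste0("c", 1:4),
                     sample_id = rep(c("s1", "s2"), each = 2),
                     group = rep(c("DS", "DFUNH"), each = 2),
                     tissue = "skin", cell_type = "CT1",
                     stringsAsFactors = FALSE)
  labeled_expression(counts, meta)
}

# small LR database with one two-subunit receptor, genes on abundant ids
fixture_lr_db <- function() {
  data.frame(
    pair_name = paste0("P", 1:5),
    pathway = rep(c("COLLAGEN", "FN1"), length.out = 5),
    ligand_genes = I(as.list(sprintf("G%04d", 61:65))),
    receptor_genes = I(lapply(1:5, function(i) {
      if (i <= 2) sprintf("G%04d", c(70 + i, 80 + i)) else sprintf("G%04d", 70 + i)
    })),
    stringsAsFactors = FALSE)
}

# planted rescue genes on well-expressed ids, one dominant cell type
fixture_rescue_plant <- function() {
  data.frame(gene = sprintf("G%04d", 41:60), cell_type = "CT1",
             direction = rep(c("up", "down"), each = 10),
             fc_unhealing = rep(c(0.5, 2.0), each = 10),
             fc_healing = rep(c(2.0, 0.5), each = 10),
             stringsAsFactors = FALSE)
}

fixture_dominant_props <- function(p1 = c(0.3, 0.3, 0.3)) {
  m <- rbind(p1, matrix(rep((1 - p1) / 7, each = 7), 7, 3))
  dimnames(m) <- list(paste0("CT", 1:8), c("DS", "DFUNH", "DFUH"))
  m
}

# noiseless transcriptional-diversity gradient with constant library size:
# cell i expresses the first k_i genes once; a housekeeping row pads the
# library so normalization cannot reorder cells
fixture_gradient_expr <- function(n_cells = 60) {
  k <- seq(31, 31 + 4 * (n_cells - 1), by = 4)
  G <- 301
  cnt <- sapply(seq_len(n_cells), function(i)
    c(rep(1, k[i]), rep(0, G - 1 - k[i]), 300 - k[i]))
  rownames(cnt) <- c(sprintf("g%03d", seq_len(G - 1)), "HK")
  colnames(cnt) <- sprintf("c%02d", seq_len(n_cells))
  meta <- data.frame(cell_id = colnames(cnt), sample_id = "s1", group = "DS",
                     tissue = "skin", cell_type = "Fibro",
                     subcluster = rep(c("early", "late"), each = n_cells / 2),
                     stringsAsFactors = FALSE)
  list(expr = normalize_counts(labeled_expression(Matrix::Matrix(cnt, sparse = TRUE), meta)),
       k = k)
}

# exact two-sided Mann-Whitney p by brute-force enumeration of all
# C(n_a + n_b, n_a) group assignments (independent oracle)
enum_wilcox_p <- function(a, b) {
  v <- c(a, b)
  n_a <- length(a)
  r <- rank(v)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(v), n_a)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  mu <- n_a * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# brute-force BH step-up definition (independent oracle)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
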