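# Independent brute-force oracles, deliberately written against the
# definitions rather than reusing package code paths.

# moving average with symmetric edge shrinkage, single chromosome
oracle_moving_average <- function(v, window) {
  n <- length(v)
  h_max <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    h <- min(h_max, i - 1, n - i)
    mean(v[(i - h):(i + h)])
  }, 0)
}

# Spearman rho by explicit ranking + Pearson product-moment formula
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# PCA scores by dense eigendecomposition of the covariance matrix
oracle_pca_scores <- function(m, k = 2) {
  mc <- scale(m, center = TRUE, scale = FALSE)
  e <- eigen(stats::cov(mc), symmetric = TRUE)
  scores <- mc %*% e$vectors[, seq_len(k), drop = FALSE]
  list(scores = scores, values = e$values)
}

# log2 fold change of de-logged means with pseudocount 1
oracle_log2fc <- function(target_values, ref_values) {
  log2((mean(expm1(target_values)) + 1) / (mean(expm1(ref_values)) + 1))
}

# build a count_dataset directly from a dense matrix + minimal metadata
make_dataset <- function(counts, stage = "normal", cell_type = "SLC1",
                         sample_id = NULL, genes = NULL) {
  n <- nrow(counts)
  cells <- tibble::tibble(
    barcode = sprintf("bc%03d", seq_len(n)),
    sample_id = sample_id %||% rep("s1", n),
    stage = if (length(stage) == 1) rep(stage, n) else stage,
    cell_type = if (length(cell_type) == 1) rep(cell_type, n) else cell_type
  )
  if (is.null(genes)) {
    genes <- synthetic_gene_annotation(max(ncol(counts), 44), seed = 99)[seq_len(ncol(counts)), ]
  }
  count_dataset(counts, cells, genes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulated cohort reused by several test files
quick_sim <- function(seed = 1, ...) {
  simulate_dataset(sim_config(
    n_samples_per_stage = c(normal = 2L, SSL = 2L, TSA = 1L, tumor = 2L),
    n_cells_per_sample = 50L, n_genes = 300L, n_continuum_genes = 40L,
    seed = seed, ...
  ))
}

# normalized_matrix built directly from a dense matrix of ln-values
make_norm <- function(values, cells = NULL, genes = NULL) {
  n <- nrow(values); g <- ncol(values)
  if (is.null(cells)) {
    cells <- tibble::tibble(barcode = sprintf("bc%03d", seq_len(n)),
                            sample_id = "s1", stage = "normal",
                            cell_type = "SLC1")
  }
  if (is.null(genes)) {
    genes <- synthetic_gene_annotation(max(g, 44), seed = 99)[seq_len(g), ]
  }
  v <- methods::as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix")
  dimnames(v) <- list(cells$barcode, genes$gene_id)
  structure(list(values = v, cells = cells, genes = genes, scale = 1e4,
                 provenance = list()), class = "normalized_matrix")
}
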