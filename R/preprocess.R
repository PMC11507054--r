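#' Quality-control filtering of cells
#'
#' Keeps cells with at least `min_genes` detected genes and a mitochondrial
#' count fraction of at most `max_mito_pct` percent. Mitochondrial genes are
#' recognised by a gene-name prefix (default `"MT-"`); if the annotation has
#' no such genes the mito filter is a no-op. Per-sample removal counts are
#' reported via a message.
#'
#' @param dataset A [count_dataset()].
#' @param min_genes Minimum number of genes with nonzero counts per cell.
#' @param max_mito_pct Maximum mitochondrial percentage (0-100).
#' @param mito_prefix Gene-name prefix marking mitochondrial genes.
#' @return The filtered [count_dataset()], with the applied parameters in
#'   `attr(, "qc")`. Errors if any sample loses all of its cells, since
#'   sample-level analyses would be undefined.
#' @export
qc_filter <- function(dataset, min_genes = 200, max_mito_pct = 20,
                      mito_prefix = "MT-") {
  stopifnot(inherits(dataset, "count_dataset"))
  assert_scalar_number(min_genes, "min_genes", lower = 0)
  assert_scalar_number(max_mito_pct, "max_mito_pct", lower = 0, upper = 100)

  detected <- rowSums(dataset$counts > 0)
  total <- rowSums(dataset$counts)
  mito_genes <- startsWith(dataset$genes$gene_name, mito_prefix)
  mito_frac <- if (any(mito_genes)) {
    m <- rowSums(dataset$counts[, mito_genes, drop = FALSE])
    ifelse(total > 0, m / total, 0)
  } else {
    rep(0, nrow(dataset$counts))
  }
  keep <- detected >= min_genes & mito_frac <= max_mito_pct / 100

  removed <- dataset$cells[!keep, ] %>% count(.data$sample_id)
  if (nrow(removed)) {
    inform(paste0("qc_filter removed cells: ",
                  paste(sprintf("%s=%d", removed$sample_id, removed$n), collapse = ", ")))
  }
  lost <- setdiff(unique(dataset$cells$sample_id),
                  unique(dataset$cells$sample_id[keep]))
  if (length(lost)) {
    abort(paste0("qc_filter would remove every cell of sample(s): ",
                 paste(lost, collapse = ", ")))
  }
  out <- count_dataset(dataset$counts[keep, , drop = FALSE],
                       dataset$cells[keep, , drop = FALSE], dataset$genes)
  attr(out, "qc") <- list(min_genes = min_genes, max_mito_pct = max_mito_pct,
                          mito_prefix = mito_prefix,
                          n_removed = sum(!keep))
  out
}

#' Library-size normalization with log transform
#'
#' Computes `ln(1 + count * scale / libsize)` per cell, the standard
#' log-normalization. The value is invariant to rescaling all counts of a
#' cell, so downstream statistics compare expression composition rather than
#' sequencing depth.
#'
#' @param dataset A [count_dataset()] (run [qc_filter()] first; cells with
#'   zero total counts are an error).
#' @param scale Scale factor (default 10,000).
#' @return An object of class `normalized_matrix`: list with `values` (sparse
#'   cells-by-genes matrix of normalized expression), `cells`, `genes`,
#'   `scale`, and `provenance` (QC parameters if present).
#' @export
normalize_counts <- function(dataset, scale = 1e4) {
  stopifnot(inherits(dataset, "count_dataset"))
  assert_scalar_number(scale, "scale", lower = 1e-12)
  libsize <- rowSums(dataset$counts)
  if (any(libsize == 0)) {
    abort(paste0(sum(libsize == 0),
                 " cell(s) have zero total counts; run qc_filter() first"))
  }
  values <- Matrix::Diagonal(x = scale / libsize) %*% dataset$counts
  values <- as(log1p(values), "CsparseMatrix")
  dimnames(values) <- dimnames(dataset$counts)
  structure(list(
    values = values,
    cells = dataset$cells,
    genes = dataset$genes,
    scale = scale,
    provenance = list(qc = attr(dataset, "qc"), scale = scale)
  ), class = "normalized_matrix")
}

#' @exportS3Method base::print
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d cells x %d genes (ln(1 + count * %g / libsize))\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Barcodes of cells matching a stage and/or cell type
#'
#' @param meta Cell metadata with `barcode`, `stage`, `cell_type` columns.
#' @param stage,cell_type Labels to keep; NULL means no restriction.
#' @return Character vector of matching barcodes.
#' @export
cells_matching <- function(meta, stage = NULL, cell_type = NULL) {
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(stage)) keep <- keep & meta$stage %in% stage
  if (!is.null(cell_type)) keep <- keep & meta$cell_type %in% cell_type
  meta$barcode[keep]
}
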