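#' Construct a multi-sample single-cell count dataset
#'
#' The universal pipeline input: a cells-by-genes matrix of raw UMI counts
#' together with per-cell metadata (sample, pathological stage, cell type) and
#' a gene annotation carrying genomic coordinates and chromosome-arm labels.
#'
#' @param counts Cells-by-genes matrix of nonnegative integer counts (dense or
#'   sparse; stored as a `dgCMatrix`). Rows are cells, columns genes.
#' @param cells Data frame with columns `barcode`, `sample_id`, `stage`,
#'   `cell_type`; one row per matrix row, barcodes unique, stages drawn from
#'   [stage_levels()].
#' @param genes Data frame with columns `gene_id`, `gene_name`, `chromosome`,
#'   `start`, `end`, `arm`; one row per matrix column. `arm` is one of
#'   [arm_levels()] or NA for unplaced genes.
#' @return An object of class `count_dataset` (a list with elements `counts`,
#'   `cells`, `genes`).
#' @seealso [simulate_dataset()], [read_counts()], [qc_filter()],
#'   [normalize_counts()]
#' @export
count_dataset <- function(counts, cells, genes) {
  cells <- as_tibble(cells)
  genes <- as_tibble(genes)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")

  need_cells <- c("barcode", "sample_id", "stage", "cell_type")
  if (!all(need_cells %in% names(cells))) {
    abort(paste0("`cells` must have columns ", paste(need_cells, collapse = ", ")))
  }
  need_genes <- c("gene_id", "gene_name", "chromosome", "start", "end", "arm")
  if (!all(need_genes %in% names(genes))) {
    abort(paste0("`genes` must have columns ", paste(need_genes, collapse = ", ")))
  }
  if (nrow(cells) != nrow(counts) || nrow(genes) != ncol(counts)) {
    abort(sprintf(
      "dimension mismatch: counts is %d x %d but %d cell and %d gene records given",
      nrow(counts), ncol(counts), nrow(cells), nrow(genes)
    ))
  }
  dup <- cells$barcode[duplicated(cells$barcode)]
  if (length(dup)) {
    abort(paste0("duplicated barcodes: ", paste(unique(dup), collapse = ", ")))
  }
  bad_stage <- setdiff(unique(cells$stage), stage_levels())
  if (length(bad_stage)) {
    abort(paste0("unknown stage label(s): ", paste(bad_stage, collapse = ", "),
                 " (expected one of ", paste(stage_levels(), collapse = ", "), ")"))
  }
  bad_arm <- setdiff(unique(genes$arm[!is.na(genes$arm)]), arm_levels())
  if (length(bad_arm)) {
    abort(paste0("unknown chromosome arm label(s): ", paste(bad_arm, collapse = ", ")))
  }
  if (any(counts@x < 0)) abort("counts must be nonnegative")

  dimnames(counts) <- list(cells$barcode, genes$gene_id)
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "count_dataset")
}

#' @exportS3Method base::print
print.count_dataset <- function(x, ...) {
  cat(sprintf("<count_dataset> %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  st <- table(factor(x$cells$stage, levels = stage_levels()))
  cat("  samples:", length(unique(x$cells$sample_id)),
      " stages:", paste(sprintf("%s=%d", names(st)[st > 0], st[st > 0]), collapse = " "), "\n")
  cat("  cell types:", paste(sort(unique(x$cells$cell_type)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_dataset <- function(x) dim(x$counts)

# Subset a count_dataset by cell barcodes (keeps gene annotation).
subset_cells <- function(dataset, barcodes) {
  keep <- dataset$cells$barcode %in% barcodes
  count_dataset(dataset$counts[keep, , drop = FALSE],
                dataset$cells[keep, , drop = FALSE],
                dataset$genes)
}
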