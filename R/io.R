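#' Write a count dataset to a MatrixMarket directory
#'
#' Writes the 10x-style triplet layout: `matrix.mtx` (genes as rows, cells as
#' columns, 1-based coordinates), `features.tsv` (gene_id, gene_name,
#' chromosome, start, end, arm), `barcodes.tsv`, and a `cells.tsv` metadata
#' table. If `truth` is given, its planted parameters are written to
#' `truth.json`.
#'
#' @param dataset A [count_dataset()].
#' @param dir Output directory, created if absent.
#' @param truth Optional `sim_truth` from [simulate_dataset()].
#' @param header Write a header line in `features.tsv` (default FALSE, the
#'   conventional headerless layout).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, truth = NULL, header = FALSE) {
  stopifnot(inherits(dataset, "count_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(dataset$counts), file.path(dir, "matrix.mtx"))
  write.table(dataset$genes, file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = header)
  writeLines(dataset$cells$barcode, file.path(dir, "barcodes.tsv"))
  write.table(dataset$cells, file.path(dir, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  if (!is.null(truth)) write_truth(truth, file.path(dir, "truth.json"))
  invisible(dir)
}

write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    samples = truth$samples,
    baseline = truth$baseline,
    beta = truth$beta,
    cnv = truth$cnv,
    programs = truth$programs
  ), path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read planted simulation truth from JSON
#'
#' @param path Path to a `truth.json` written by [write_dataset()].
#' @return A `sim_truth` object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tidy_mask <- function(df) {
    if (is.null(df) || (is.data.frame(df) && nrow(df) == 0)) {
      return(tibble(arm = character(), copy_ratio = numeric(),
                    cells = list(), genes = list()))
    }
    as_tibble(df)
  }
  structure(list(
    samples = as_tibble(x$samples),
    baseline = as_tibble(x$baseline),
    beta = as_tibble(x$beta),
    cnv = tidy_mask(x$cnv),
    programs = if (is.null(x$programs) || length(x$programs) == 0) {
      tibble(program = character(), log2_elevation = numeric(),
             genes = list(), cells = list())
    } else as_tibble(x$programs)
  ), class = "sim_truth")
}

#' Read a count dataset from a MatrixMarket directory
#'
#' Expects `matrix.mtx` + `features.tsv` + `barcodes.tsv`, plus `cells.tsv`
#' with per-cell metadata (barcode, sample_id, stage, cell_type). The matrix
#' is stored genes-by-cells (the dominant single-cell dialect); use
#' `transpose = TRUE` for files written cells-by-genes.
#'
#' @param dir Directory containing the files.
#' @param transpose If TRUE the .mtx file has cells as rows.
#' @return A [count_dataset()].
#' @export
read_counts <- function(dir, transpose = FALSE) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv", "cells.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")))

  m <- tryCatch(
    # a body/header mismatch only warns in the reader; promote it to an error
    withCallingHandlers(
      Matrix::readMM(paths[1]),
      warning = function(w) abort(paste0("failed to parse ", paths[1], ": ",
                                         conditionMessage(w)))
    ),
    error = function(e) {
      abort(paste0("failed to parse ", paths[1], ": ", conditionMessage(e)))
    }
  )
  if (!transpose) m <- Matrix::t(m)

  first <- readLines(paths[2], n = 1)
  has_header <- grepl("^gene_id\t", first)
  genes <- read.delim(paths[2], header = has_header, sep = "\t",
                      colClasses = "character")
  if (!has_header) {
    if (ncol(genes) < 6) abort("features.tsv must have 6 columns: gene_id, gene_name, chromosome, start, end, arm")
    names(genes)[1:6] <- c("gene_id", "gene_name", "chromosome", "start", "end", "arm")
  }
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  genes$arm[genes$arm %in% c("NA", "")] <- NA_character_

  barcodes <- readLines(paths[3])
  dup <- unique(barcodes[duplicated(barcodes)])
  if (length(dup)) abort(paste0("duplicated barcode(s) in barcodes.tsv: ",
                                paste(dup, collapse = ", ")))
  cells <- as_tibble(read.delim(paths[4], sep = "\t"))
  if (!identical(cells$barcode, barcodes)) {
    cells <- cells[match(barcodes, cells$barcode), ]
    if (anyNA(cells$barcode)) abort("cells.tsv does not cover every barcode in barcodes.tsv")
  }
  if (nrow(m) != length(barcodes) || ncol(m) != nrow(genes)) {
    abort(sprintf("dimension mismatch: matrix is %d x %d after orientation but %d barcodes and %d features given",
                  nrow(m), ncol(m), length(barcodes), nrow(genes)))
  }
  count_dataset(m, cells, genes)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#' Duplicate genes within a set are removed with a warning; genes may be
#' uppercased to ease symbol matching.
#'
#' @param path Path to a .gmt file.
#' @param uppercase Uppercase gene symbols (default FALSE).
#' @return Tibble with columns `set`, `description`, `genes` (list column);
#'   an empty file yields an empty tibble.
#' @export
read_gmt <- function(path, uppercase = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(set = character(), description = character(), genes = list()))
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("GMT line %d has %d field(s); need name, description and at least one gene",
                    i, length(f)))
    }
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    if (uppercase) g <- toupper(g)
    if (anyDuplicated(g)) {
      warn(sprintf("GMT set '%s': removed %d duplicate gene(s)", f[1], sum(duplicated(g))))
      g <- unique(g)
    }
    tibble(set = f[1], description = f[2], genes = list(g))
  })
  bind_rows(rows)
}

#' Write gene sets to a GMT file
#'
#' @param sets Tibble as returned by [read_gmt()] (columns `set`,
#'   `description`, `genes`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set[i], sets$description[i], sets$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
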