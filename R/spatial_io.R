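#' Validate a cell metadata table
#'
#' Checks the per-cell table contract used throughout the package: one row
#' per segmented cell with micrometre coordinates, the FOV / tissue-core /
#' patient hierarchy, a region label (`T` tumor core, `B` invasive boundary,
#' `N` adjacent normal) and a cell-type label.
#'
#' @param cells data.frame with columns `cell_id`, `x_um`, `y_um`, `fov_id`,
#'   `core_id`, `patient_id`, `region`, `cell_type`.
#' @return `cells`, invisibly, with character columns coerced to character.
#' @export
validate_cells <- function(cells) {
  req <- c("cell_id", "x_um", "y_um", "fov_id", "core_id", "patient_id",
           "region", "cell_type")
  miss <- setdiff(req, names(cells))
  .assert(length(miss) == 0, "cells table is missing column(s): %s",
          paste(miss, collapse = ", "))
  for (cl in setdiff(req, c("x_um", "y_um")))
    cells[[cl]] <- as.character(cells[[cl]])
  dup <- cells$cell_id[duplicated(cells$cell_id)]
  .assert(length(dup) == 0, "duplicate cell_id(s): %s",
          paste(unique(dup)[1:min(3, length(unique(dup)))], collapse = ", "))
  .assert(all(is.finite(cells$x_um)) && all(is.finite(cells$y_um)),
          "non-finite coordinates in cells table")
  bad <- setdiff(unique(cells$region), REGION_LEVELS)
  .assert(length(bad) == 0, "unknown region label(s): %s (expected T/B/N)",
          paste(bad, collapse = ", "))
  # each FOV must sit in exactly one (core, patient, region)
  key <- unique(cells[, c("fov_id", "core_id", "patient_id", "region")])
  multi <- key$fov_id[duplicated(key$fov_id)]
  .assert(length(multi) == 0,
          "fov_id mapped to more than one (core, patient, region): %s",
          paste(unique(multi), collapse = ", "))
  invisible(cells)
}

.validate_counts <- function(counts, cells = NULL) {
  .assert(is(counts, "Matrix") || is.matrix(counts),
          "counts must be a (sparse) matrix")
  .assert(nrow(counts) > 0 && ncol(counts) > 0,
          "counts matrix is empty (%d genes x %d cells)",
          nrow(counts), ncol(counts))
  v <- if (is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  .assert(all(v >= 0), "negative entries in counts matrix")
  .assert(all(v == round(v)), "non-integer entries in counts matrix")
  if (!is.null(cells)) {
    .assert(ncol(counts) == nrow(cells),
            "counts has %d cells but cells table has %d rows",
            ncol(counts), nrow(cells))
    .assert(identical(colnames(counts), cells$cell_id),
            "counts column order does not match cells$cell_id")
  }
  invisible(counts)
}

#' Write a spatial dataset to a directory
#'
#' Layout: `cells.tsv` (tab-separated, header, '.' decimal), `matrix.mtx`
#' (MatrixMarket coordinate, integer, genes x cells), `genes.tsv` and
#' `barcodes.tsv` (one identifier per line), optionally `survival.tsv`.
#' Output is byte-deterministic for identical inputs.
#'
#' @param cells validated cell table (see [validate_cells()]).
#' @param counts sparse integer gene x cell matrix with dimnames.
#' @param dir output directory, created if needed.
#' @param survival optional data.frame(patient_id, time_months, event).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(cells, counts, dir, survival = NULL) {
  cells <- validate_cells(cells)
  .validate_counts(counts, cells)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cells, file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  .write_mtx_integer(counts, file.path(dir, "matrix.mtx"))
  if (!is.null(survival)) {
    .assert(all(c("patient_id", "time_months", "event") %in% names(survival)),
            "survival table needs patient_id, time_months, event")
    write.table(survival, file.path(dir, "survival.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

# integer-typed MatrixMarket coordinate writer (the dataset contract is
# integer-typed; Matrix::writeMM emits a real-typed header)
.write_mtx_integer <- function(counts, path) {
  m <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  trip <- Matrix::summary(m)  # column-major (i, j, x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), nrow(trip)), con)
  if (nrow(trip) > 0)
    writeLines(sprintf("%d %d %d", trip$i, trip$j, as.integer(trip$x)), con)
  invisible(path)
}

#' Read a spatial dataset from a directory
#'
#' Counterpart of [write_dataset()]; validates all invariants (order-aligned
#' barcodes, unique cell ids, known region labels, matching dimensions).
#'
#' @param dir directory holding `cells.tsv`, `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` and optionally `survival.tsv`.
#' @return list with `cells`, `counts` and (possibly `NULL`) `survival`.
#' @export
read_dataset <- function(dir) {
  for (f in c("cells.tsv", "matrix.mtx", "genes.tsv", "barcodes.tsv"))
    .assert(file.exists(file.path(dir, f)), "missing %s in %s", f, dir)
  cells <- read.delim(file.path(dir, "cells.tsv"), colClasses = "character")
  cells$x_um <- as.numeric(cells$x_um)
  cells$y_um <- as.numeric(cells$y_um)
  cells <- validate_cells(cells)
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  .assert(nrow(counts) == length(genes),
          "matrix.mtx has %d rows but genes.tsv lists %d genes",
          nrow(counts), length(genes))
  .assert(ncol(counts) == length(barcodes),
          "matrix.mtx has %d columns but barcodes.tsv lists %d cells",
          ncol(counts), length(barcodes))
  missing_bc <- setdiff(barcodes, cells$cell_id)
  .assert(length(missing_bc) == 0,
          "barcode(s) absent from cells.tsv: %s",
          paste(missing_bc[1:min(3, length(missing_bc))], collapse = ", "))
  .assert(identical(barcodes, cells$cell_id),
          "barcodes.tsv and cells.tsv disagree in cell order")
  dimnames(counts) <- list(genes, barcodes)
  .validate_counts(counts, cells)
  surv <- NULL
  if (file.exists(file.path(dir, "survival.tsv"))) {
    surv <- read.delim(file.path(dir, "survival.tsv"),
                       colClasses = c(patient_id = "character"))
  }
  list(cells = cells, counts = counts, survival = surv)
}

#' Remove low-transcript cells
#'
#' Drops cells whose total transcript count falls below `min_transcripts`
#' from both the cell table and the count matrix, the standard quality gate
#' for imaging-based platforms where poorly segmented cells carry few
#' transcripts. The default of 20 follows CosMx convention.
#'
#' @param cells,counts aligned cell table and gene x cell count matrix.
#' @param min_transcripts minimum per-cell total (inclusive) to retain.
#' @return list(cells, counts, report) where `report` tabulates cells before
#'   and after per FOV and echoes the threshold.
#' @export
qc_filter_cells <- function(cells, counts, min_transcripts = 20) {
  cells <- validate_cells(cells)
  .validate_counts(counts, cells)
  .assert(min_transcripts >= 0, "min_transcripts must be >= 0")
  totals <- Matrix::colSums(counts)
  keep <- totals >= min_transcripts
  .assert(any(keep),
          "QC removed all %d cells at min_transcripts = %s; review threshold",
          length(keep), format(min_transcripts))
  before <- table(factor(cells$fov_id, levels = unique(cells$fov_id)))
  after <- table(factor(cells$fov_id[keep], levels = unique(cells$fov_id)))
  report <- data.frame(fov_id = names(before),
                       n_before = as.integer(before),
                       n_after = as.integer(after),
                       row.names = NULL)
  attr(report, "min_transcripts") <- min_transcripts
  list(cells = cells[keep, , drop = FALSE],
       counts = counts[, keep, drop = FALSE],
       report = report)
}

#' Library-size normalization with log transform
#'
#' Scales each cell to `target_total` counts then applies
#' `log(pseudo + x)`; with the default `pseudo = 1` this is the familiar
#' log1p(CPX) view, a monotone variance-stabilizing transform adequate for
#' the rank-based differential tests and correlations downstream.
#'
#' @param counts gene x cell count matrix (QC-filtered; zero-total cells are
#'   an error).
#' @param target_total per-cell total after scaling.
#' @param pseudo pseudocount inside the log.
#' @return normalized matrix, sparse when `pseudo == 1`.
#' @export
normalize_counts <- function(counts, target_total = 500, pseudo = 1) {
  .validate_counts(counts)
  totals <- Matrix::colSums(counts)
  zero <- colnames(counts)[totals == 0]
  .assert(length(zero) == 0,
          "cell(s) with zero total counts (run qc_filter_cells first): %s",
          paste(zero[1:min(3, length(zero))], collapse = ", "))
  scaled <- as(counts %*% Matrix::Diagonal(x = target_total / totals),
               "CsparseMatrix")
  dimnames(scaled) <- dimnames(counts)
  if (pseudo == 1) {
    out <- scaled
    out@x <- log1p(out@x)
    out
  } else {
    .assert(pseudo > 0, "pseudo must be > 0")
    log(pseudo + as.matrix(scaled))
  }
}
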