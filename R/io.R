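# Readers and writers for the formats the tool touches: dense CSV/TSV count
# matrices, MatrixMarket triplets with barcode/feature companions (10x-style
# exports), marker matrices, per-spot cell counts and coordinates.

read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, check.names = FALSE, row.names = 1)
}

#' Read a spot-level count matrix
#'
#' Dense CSV/TSV (first column = row ids, header = column ids) or
#' MatrixMarket `.mtx` with `features.tsv` and `barcodes.tsv` companions in
#' the same directory (genes in rows, spots in columns, as exported by 10x
#' pipelines). The result is always gene x spot; set
#' `orientation = "spot_by_gene"` when a dense file stores spots in rows.
#'
#' @param path file path (`.csv`, `.tsv`, or `.mtx`).
#' @param orientation orientation of a dense file.
#' @return validated gene x spot integer matrix.
#' @export
read_counts <- function(path,
                        orientation = c("gene_by_spot", "spot_by_gene")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    feat <- file.path(dir, "features.tsv")
    bc <- file.path(dir, "barcodes.tsv")
    if (!file.exists(feat) || !file.exists(bc))
      stop("features.tsv / barcodes.tsv not found next to ", path)
    rownames(m) <- read.delim(feat, header = FALSE)[[1]]
    colnames(m) <- read.delim(bc, header = FALSE)[[1]]
  } else {
    m <- as.matrix(read_table_auto(path))
    if (orientation == "spot_by_gene") m <- t(m)
  }
  validate_counts(m)
}

#' Write a count matrix
#'
#' CSV/TSV (by extension) or MatrixMarket with companion `features.tsv` /
#' `barcodes.tsv` files.
#'
#' @param counts gene x spot matrix.
#' @param path output path (`.csv`, `.tsv` or `.mtx`).
#' @export
write_counts <- function(counts, path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(counts), file.path(dir, "features.tsv"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    write.table(counts, path, sep = sep, quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' Read a binary marker matrix
#'
#' CSV/TSV with genes in rows and types in columns; a zero dummy column is
#' appended when absent (with a message).
#'
#' @param path file path.
#' @return validated marker matrix with a `"dummy_index"` attribute.
#' @export
read_marker_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_markers(as.matrix(read_table_auto(path)))
}

#' @rdname read_marker_matrix
#' @param markers marker matrix to write.
#' @export
write_marker_matrix <- function(markers, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(markers, path, sep = sep, quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read per-spot cell counts
#'
#' Two-column CSV/TSV (spot id, count). Spot order in the file is
#' irrelevant; ids are the join key.
#'
#' @param path file path.
#' @param spot_ids optional spot ids to validate and order against; an error
#'   names the missing spots.
#' @return named numeric vector of positive counts.
#' @export
read_cell_counts <- function(path, spot_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read_table_auto(path)
  counts <- setNames(as.numeric(tab[[1]]), rownames(tab))
  if (anyNA(counts) || any(counts <= 0))
    stop("cell counts must be positive numbers")
  if (!is.null(spot_ids)) {
    missing <- setdiff(spot_ids, names(counts))
    if (length(missing))
      stop("cell counts missing for spot(s): ",
           paste(head(missing, 5), collapse = ", "))
    counts <- counts[spot_ids]
  }
  counts
}

#' Read spot coordinates
#'
#' CSV/TSV with spot ids in the first column and two numeric coordinate
#' columns (array coordinates as exported; used only for neighbour
#' finding).
#'
#' @param path file path.
#' @param spot_ids optional spot ids to validate and order against.
#' @return matrix with columns `x`, `y` and spot ids as rownames.
#' @export
read_coordinates <- function(path, spot_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read_table_auto(path)
  if (ncol(tab) < 2) stop("coordinates need two numeric columns")
  xy <- as.matrix(tab[, 1:2])
  colnames(xy) <- c("x", "y")
  if (anyNA(xy) || !is.numeric(xy)) stop("non-numeric coordinates")
  if (!is.null(spot_ids)) {
    missing <- setdiff(spot_ids, rownames(xy))
    if (length(missing))
      stop("coordinates missing for spot(s): ",
           paste(head(missing, 5), collapse = ", "))
    xy <- xy[spot_ids, , drop = FALSE]
  }
  xy
}
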