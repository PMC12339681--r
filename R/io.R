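#' Read and write pipeline tables
#'
#' All pipeline tables (field measurements, well summaries, compound
#' results, ground truth) travel as tab-separated text with a header row.
#' Writing is deterministic: the same data.frame always produces
#' byte-identical files.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `write_screen_table` returns `path` invisibly;
#'   `read_screen_table` returns a data.frame.
#' @export
write_screen_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_screen_table
#' @export
read_screen_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a count matrix as an MTX triplet with metadata
#'
#' Writes `matrix.mtx` (MatrixMarket sparse triplet), `genes.tsv`,
#' `wells.tsv` and `metadata.tsv` into `dir`.
#'
#' @param counts genes x wells integer matrix with dimnames.
#' @param meta well metadata data.frame (see [simulate_counts()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, meta, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "wells.tsv"))
  write_screen_table(meta, file.path(dir, "metadata.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `wells.tsv`,
#'   `metadata.tsv`.
#' @return list with dense integer `counts` (dimnames restored) and
#'   `meta`.
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "wells.tsv")))
  list(counts = m,
       meta = read_screen_table(file.path(dir, "metadata.tsv")))
}

#' Write and read a 3-channel field image as multi-page TIFF
#'
#' Channel order: nuclei, IBA1, pHrodo.
#'
#' @param image height x width x 3 array in [0, 1].
#' @param path TIFF file path.
#' @return `write_field_tiff` returns `path` invisibly;
#'   `read_field_tiff` returns a list of matrices `nuclei`, `iba1`,
#'   `phrodo`.
#' @export
write_field_tiff <- function(image, path) {
  pages <- lapply(seq_len(dim(image)[3]), function(k) image[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stats::setNames(pages[1:3], c("nuclei", "iba1", "phrodo"))
}
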