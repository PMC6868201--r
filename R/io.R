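# Delimited-text matrix I/O. Rows are samples, columns features; comma or
# tab delimited; a header row is auto-detected (non-numeric first line).

#' Read a sample matrix from delimited text
#'
#' @param path File path. The delimiter (comma, tab, or whitespace) is
#'   sniffed from the first line; a header row is detected when the first
#'   line contains non-numeric fields.
#' @return Numeric matrix (rows = samples).
#' @export
read_sample_matrix <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty input file: ", path, call. = FALSE)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else
         if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  header <- anyNA(suppressWarnings(as.numeric(fields)))
  X <- utils::read.table(path, sep = sep, header = header)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("non-finite entries in ", path, call. = FALSE)
  unname(X)
}

#' Write a sample matrix as delimited text
#'
#' Floats are printed with 17 significant digits so a write/read round trip
#' reproduces the matrix exactly.
#'
#' @param X Numeric matrix.
#' @param path Output path.
#' @param sep Field delimiter (default comma).
#' @export
write_sample_matrix <- function(X, path, sep = ",") {
  X <- as.matrix(X)
  lines <- apply(X, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = sep)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Write an empirical correlation integral as two-column text
#'
#' @param ecdf An `fci_ecdf` object.
#' @param path Output path.
#' @param sep Field delimiter (default comma).
#' @export
write_ecdf <- function(ecdf, path, sep = ",") {
  stopifnot(inherits(ecdf, "fci_ecdf"))
  writeLines(sprintf("%.17g%s%.17g", ecdf$radii, sep, ecdf$cdf), path)
  invisible(path)
}

#' Write a blob image as a plain PGM (P2) file
#'
#' Pixel values are scaled linearly to the integer range 0..255 for easy
#' visual inspection with any image viewer.
#'
#' @param img Numeric matrix (an image from [render_blob()], or one row of
#'   [gen_blob_images()] reshaped back to `l` x `l`).
#' @param path Output path.
#' @export
write_pgm <- function(img, path) {
  img <- as.matrix(img)
  top <- max(img, 1e-12)
  pix <- round(pmin(pmax(img / top, 0), 1) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  writeLines(apply(pix, 1L, paste, collapse = " "), con)
  invisible(path)
}
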