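#' Contact matrix object
#'
#' A symmetric sparse matrix of contact counts over a bin table, with a
#' per-bin validity mask and (after correction) a per-bin bias vector.
#'
#' @param bins A bin table (see [digest_genome()]).
#' @param counts Symmetric non-negative matrix (dense or `Matrix` sparse)
#'   with one row/column per bin.
#' @param mask Logical per-bin vector, `TRUE` = valid; defaults to all
#'   valid.
#' @param biases Per-bin positive bias vector, or `NULL` before correction.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, counts, mask = NULL, biases = NULL) {
  validate_bins(bins)
  n <- nrow(bins)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != n || ncol(counts) != n) {
    stop("counts must be ", n, " x ", n, " to match the bin table")
  }
  if (!Matrix::isSymmetric(counts, tol = 0)) stop("counts must be symmetric")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(is.logical(mask), length(mask) == n)
  if (!is.null(biases)) {
    stopifnot(length(biases) == n)
    if (any(biases[mask] <= 0, na.rm = TRUE)) stop("biases must be positive")
  }
  structure(list(bins = bins, counts = counts, mask = mask, biases = biases),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", nrow(x$bins), " bins on ",
      length(unique(x$bins$chrom)), " chromosome(s); total counts ",
      format(matrix_total(x)), "; ", sum(!x$mask), " masked bin(s); ",
      if (is.null(x$biases)) "uncorrected" else "ICE-corrected", "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

#' Total contact count of a matrix
#'
#' Sum over the upper triangle plus diagonal (each pair of bins counted
#' once), i.e. the number of pairs that built an integer-count matrix.
#'
#' @param m A `contact_matrix`.
#' @return A scalar.
#' @export
matrix_total <- function(m) {
  (sum(m$counts) + sum(Matrix::diag(m$counts))) / 2
}

#' Per-bin total counts
#'
#' Row sums of the symmetric count matrix (the bin "coverage" used by the
#' low-count threshold and by ICE).
#'
#' @param m A `contact_matrix`.
#' @param masked_as_na Report masked bins as `NA` instead of their raw sum.
#' @return Numeric vector, one value per bin.
#' @export
bin_totals <- function(m, masked_as_na = FALSE) {
  tot <- Matrix::rowSums(m$counts)
  if (masked_as_na) tot[!m$mask] <- NA_real_
  tot
}

#' Write / read a contact matrix
#'
#' The on-disk form is a pair of plain-text files: `<path>` holds the
#' upper-triangle triplets (`bin_i  bin_j  count`, 1-based ids, i <= j,
#' tab-separated, with a header) and `<path>.bins.bed` is a BED4+2 sidecar
#' (`chrom start end bin_id mask bias`). The round trip is lossless,
#' bit-identical for integer counts.
#'
#' @param m A `contact_matrix`.
#' @param path Output path for the triplet file; the bin sidecar gets the
#'   suffix `.bins.bed`.
#' @return `write_matrix`: `path`, invisibly. `read_matrix`: a
#'   `contact_matrix`.
#' @export
write_matrix <- function(m, path) {
  tri <- Matrix::triu(m$counts)
  tt <- Matrix::summary(tri)
  tt <- tt[order(tt$i, tt$j), , drop = FALSE]
  trip <- tibble(bin_i = tt$i, bin_j = tt$j, count = tt$x)
  readr::write_tsv(trip, path, progress = FALSE)
  bed <- mutate(m$bins,
    mask = as.integer(m$mask),
    bias = if (is.null(m$biases)) NA_real_ else m$biases
  )
  readr::write_tsv(bed, paste0(path, ".bins.bed"), col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  bed_path <- paste0(path, ".bins.bed")
  if (!file.exists(bed_path)) stop("bin sidecar not found: ", bed_path)
  bed <- readr::read_tsv(bed_path,
                         col_names = c("chrom", "start", "end", "bin_id",
                                       "mask", "bias"),
                         show_col_types = FALSE, progress = FALSE)
  bins <- select(bed, "chrom", "start", "end", "bin_id")
  validate_bins(bins)
  n <- nrow(bins)

  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop("malformed triplet line ", bad[1] + 1L, " in ", path)
  }
  fm <- matrix(suppressWarnings(as.numeric(unlist(fields))),
               ncol = 3, byrow = TRUE)
  if (anyNA(fm)) {
    bad <- which(rowSums(is.na(fm)) > 0)[1]
    stop("malformed triplet line ", bad + 1L, " in ", path)
  }
  i <- pmin(fm[, 1], fm[, 2])
  j <- pmax(fm[, 1], fm[, 2])
  if (any(i < 1 | j > n)) stop("triplet bin id outside bin table in ", path)
  key <- paste(i, j)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate entry for bin pair (", d, ") in ", path,
         "; symmetric duplicates are not allowed")
  }
  upper <- Matrix::sparseMatrix(i = i, j = j, x = fm[, 3], dims = c(n, n))
  counts <- upper + Matrix::t(upper)
  Matrix::diag(counts) <- Matrix::diag(counts) / 2
  biases <- if (all(is.na(bed$bias))) NULL else bed$bias
  contact_matrix(bins, counts, mask = bed$mask == 1L, biases = biases)
}
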