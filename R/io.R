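#' Read and write the standard interval formats used by the pipeline
#'
#' All on-disk coordinates are 0-based half-open (BED convention), matching
#' the in-memory representation, so readers and writers are round-trip exact.
#'
#' @param path File path.
#' @return A tibble; loop files return a [loop_set()].
#' @name loopstack-io
NULL

#' @rdname loopstack-io
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path,
    sep = "\t", header = FALSE,
    col.names = c("chrom", "size"),
    colClasses = c("character", "numeric")
  )
  tibble::as_tibble(df)
}

#' @rdname loopstack-io
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write_tsv_plain(as_chrom_sizes(chrom_sizes), path, col_names = FALSE)
}

#' @rdname loopstack-io
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- nm[seq_len(min(ncol(df), 6))]
  tibble::as_tibble(df)
}

#' @rdname loopstack-io
#' @param bed A tibble with at least chrom/start/end columns.
#' @export
write_bed <- function(bed, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(bed))
  write_tsv_plain(bed[, keep], path, col_names = FALSE)
}

#' @rdname loopstack-io
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  names(df) <- c(
    "chrom", "start", "end", "name", "score", "strand",
    "signalValue", "pValue", "qValue", "peak"
  )[seq_len(ncol(df))]
  tibble::as_tibble(df)
}

#' @rdname loopstack-io
#' @param peaks narrowPeak tibble (BED6+4).
#' @export
write_narrowpeak <- function(peaks, path) {
  cols <- c(
    "chrom", "start", "end", "name", "score", "strand",
    "signalValue", "pValue", "qValue", "peak"
  )
  write_tsv_plain(peaks[, cols], path, col_names = FALSE)
}

#' @rdname loopstack-io
#' @param condition Condition label stored on the returned loop set.
#' @param total_valid_pairs Library-size metadata; defaults to the score sum.
#' @export
read_bedpe <- function(path, condition = NA_character_, total_valid_pairs = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  names(df) <- c(
    "chrom1", "start1", "end1", "chrom2", "start2", "end2",
    "name", "score", "q", "pets"
  )[seq_len(ncol(df))]
  loop_set(tibble::as_tibble(df),
    condition = condition,
    total_valid_pairs = total_valid_pairs
  )
}

#' @rdname loopstack-io
#' @param loops A [loop_set()].
#' @export
write_bedpe <- function(loops, path) {
  out <- tibble::as_tibble(loops)
  if (!"name" %in% names(out)) out$name <- paste0("loop", seq_len(nrow(out)))
  if (!"q" %in% names(out)) out$q <- 1
  out$q[is.na(out$q)] <- 1
  if (!"pets" %in% names(out)) out$pets <- out$score
  cols <- c(
    "chrom1", "start1", "end1", "chrom2", "start2", "end2",
    "name", "score", "q", "pets"
  )
  write_tsv_plain(out[, cols], path, col_names = FALSE)
}

#' @rdname loopstack-io
#' @export
read_expression <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE))
}

#' Read a contact matrix from dense or triplet TSV
#'
#' Dense files hold the square matrix; triplet files hold three columns
#' (bin1, bin2, value) with 1-based bin indices of the upper triangle.
#'
#' @param path File path.
#' @param format `"dense"` or `"triplet"`.
#' @param n_bins Matrix dimension, required for triplet input.
#' @return A symmetric numeric matrix.
#' @export
read_contact_matrix <- function(path, format = c("dense", "triplet"), n_bins = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    return(m)
  }
  assert_that(!is.null(n_bins), "`n_bins` is required for triplet input")
  tr <- utils::read.table(path,
    sep = "\t", header = FALSE,
    col.names = c("bin1", "bin2", "value")
  )
  m <- matrix(0, n_bins, n_bins)
  m[cbind(tr$bin1, tr$bin2)] <- tr$value
  m[cbind(tr$bin2, tr$bin1)] <- tr$value
  m
}

#' @rdname read_contact_matrix
#' @param mat Symmetric matrix to write (dense TSV).
#' @export
write_contact_matrix <- function(mat, path) {
  utils::write.table(mat, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
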