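# Internal helpers: deterministic per-label RNG streams, coordinate
# conversions, light-weight assertions.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_bad <- function(msg) stop(msg, call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort_bad(msg)
  invisible(TRUE)
}

# Stable 31-bit hash of a character label (polynomial rolling hash kept in
# double precision; all intermediates < 2^53 so arithmetic is exact).
label_hash <- function(label) {
  ints <- utf8ToInt(label)
  h <- 0
  for (k in ints) h <- (h * 131 + k) %% 2147483647
  h
}

# Derive a child seed from a master seed and a label.  One independent RNG
# stream per output file/component: adding a new output never perturbs the
# draws of existing ones.
derive_seed <- function(seed, label) {
  as.integer((seed * 48271 + label_hash(label)) %% 2147483647)
}

with_stream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, label))
  force(code)
}

# chrom sizes: accept a two-column data frame (chrom, size) or a named
# numeric vector; returns a tibble.
as_chrom_sizes <- function(chrom_sizes) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- tibble::tibble(
      chrom = names(chrom_sizes),
      size = unname(chrom_sizes)
    )
  }
  assert_that(
    is.data.frame(chrom_sizes) && ncol(chrom_sizes) >= 2,
    "`chrom_sizes` must be a data frame (chrom, size) or a named numeric vector"
  )
  out <- tibble::as_tibble(chrom_sizes[, 1:2])
  names(out) <- c("chrom", "size")
  assert_that(nrow(out) > 0, "`chrom_sizes` is empty")
  assert_that(all(out$size > 0), "chromosome sizes must be positive")
  out$chrom <- as.character(out$chrom)
  out
}

# 0-based half-open intervals -> GRanges (1-based closed internally).
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Number format that is stable across runs (fixed notation, no scientific).
fmt_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

write_tsv_plain <- function(df, path, col_names = TRUE) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  }
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = col_names
  )
  invisible(path)
}
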