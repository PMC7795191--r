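#' Two-window sliding concentration features
#'
#' For every centered bin of the binned genome, computes each attribute's
#' concentration (attribute mass divided by window width in bp) in an inner
#' and an outer window centered on the bin. Windows are whole numbers of
#' bins; the mass is the sum of the attribute over the bins fully inside
#' the window. Centers whose outer window leaves the chromosome are
#' dropped. For span attributes (bp per bin) the concentration lies in
#' [0, 1].
#'
#' @param table A `genome_bins` table.
#' @param attrs Attribute column names.
#' @param inner,outer Window widths in bp; multiples of the bin width with
#'   `outer >= inner`.
#' @return A tibble with `chrom`, `start`, `end` and
#'   `<attr>_inner` / `<attr>_outer` concentration columns.
#' @export
two_window_features <- function(table, attrs, inner, outer) {
  w <- bin_width_of(table)
  assert_that(outer >= inner, "`outer` window must be at least `inner`")
  assert_that(inner %% w == 0 && outer %% w == 0,
    "windows must be multiples of the bin width")
  k_in <- as.integer(inner / w)
  k_out <- as.integer(outer / w)
  window_sum <- function(x, k) {
    if (k == 1) {
      return(x)
    }
    cs <- cumsum(c(0, x))
    n <- length(x)
    # window of k bins with the center bin at position ceiling(k / 2)
    left <- ceiling(k / 2) - 1L
    from <- seq_len(n) - left
    to <- from + k - 1L
    out <- rep(NA_real_, n)
    ok <- from >= 1 & to <= n
    out[ok] <- cs[to[ok] + 1L] - cs[from[ok]]
    out
  }
  parts <- lapply(split(seq_len(nrow(table)), table$chrom), function(idx) {
    sub <- table[idx, , drop = FALSE]
    res <- tibble::tibble(chrom = sub$chrom, start = sub$start, end = sub$end)
    for (a in attrs) {
      res[[paste0(a, "_inner")]] <- window_sum(sub[[a]], k_in) / inner
      res[[paste0(a, "_outer")]] <- window_sum(sub[[a]], k_out) / outer
    }
    res[complete.cases(res), , drop = FALSE]
  })
  out <- dplyr::bind_rows(parts)
  structure(out, inner = inner, outer = outer, class = class(tibble::tibble()))
}

#' Class schemes for expression and interaction levels
#'
#' `"fpkm2"` splits at 1 FPKM (`<1` vs `>=1`); `"fpkm3"` uses `[0,1)`,
#' `[1,30]`, `(30,Inf)`; `"interaction2"` splits at the mean interaction
#' score with ties assigned to the lower class.
#'
#' @param scheme Scheme name.
#' @return A `class_scheme` object consumed by [label_bins()].
#' @export
class_scheme <- function(scheme = c("fpkm2", "fpkm3", "interaction2")) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme), class = "class_scheme")
}

#' Label bins by expression or interaction class
#'
#' @param table A `genome_bins` table (or any tibble) with the value column.
#' @param scheme A [class_scheme()].
#' @param column Value column (FPKM or interaction score).
#' @return Factor of class labels, one per row of `table`.
#' @export
label_bins <- function(table, scheme, column) {
  assert_that(inherits(scheme, "class_scheme"), "unknown class scheme")
  x <- table[[column]]
  lab <- switch(scheme$scheme,
    fpkm2 = ifelse(x < 1, "<1", ">=1"),
    fpkm3 = dplyr::case_when(x < 1 ~ "<1", x <= 30 ~ "1-30", TRUE ~ ">30"),
    interaction2 = ifelse(x <= mean(x), "low", "high")
  )
  factor(lab, levels = switch(scheme$scheme,
    fpkm2 = c("<1", ">=1"),
    fpkm3 = c("<1", "1-30", ">30"),
    interaction2 = c("low", "high")
  ))
}
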