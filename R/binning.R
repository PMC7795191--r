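#' Tile a genome into uniform bins
#'
#' Builds the scaffold of the uniform binned-genome table: every chromosome
#' is tiled with fixed-width bins (0-based half-open), the last bin truncated
#' at the chromosome end. Score and span attributes are added with
#' [overlay_score()], [overlay_span()] and [anchor_strength()].
#'
#' @param chrom_sizes Two-column data frame (chrom, size) or named numeric
#'   vector of chromosome lengths in bp.
#' @param bin_width Bin width in bp (default 1000).
#' @return A `genome_bins` tibble with columns `chrom`, `start`, `end`.
#' @examples
#' bin_genome(c(chr1 = 2500), bin_width = 1000)
#' @export
bin_genome <- function(chrom_sizes, bin_width = 1000) {
  assert_that(is.numeric(bin_width) && length(bin_width) == 1 && bin_width > 0,
    "`bin_width` must be a single positive number")
  cs <- as_chrom_sizes(chrom_sizes)
  bins <- purrr::map2_dfr(cs$chrom, cs$size, function(ch, len) {
    starts <- seq(0, len - 1, by = bin_width)
    tibble::tibble(chrom = ch, start = starts, end = pmin(starts + bin_width, len))
  })
  structure(bins,
    bin_width = bin_width,
    chrom_sizes = cs,
    class = c("genome_bins", class(tibble::tibble()))
  )
}

bin_width_of <- function(bins) attr(bins, "bin_width")

restore_bins <- function(out, template) {
  structure(out,
    bin_width = attr(template, "bin_width"),
    chrom_sizes = attr(template, "chrom_sizes"),
    class = class(template)
  )
}

check_known_chroms <- function(bins, intervals) {
  unknown <- setdiff(unique(intervals$chrom), unique(bins$chrom))
  assert_that(length(unknown) == 0,
    paste("intervals on unknown chromosome(s):", paste(unknown, collapse = ", ")))
}

# findOverlaps between the bin tiling and a set of intervals; returns a
# tibble of (bin row index, interval row index).
bin_interval_hits <- function(bins, intervals) {
  hits <- GenomicRanges::findOverlaps(
    intervals_to_granges(bins),
    intervals_to_granges(intervals)
  )
  tibble::tibble(
    bin = S4Vectors::queryHits(hits),
    iv = S4Vectors::subjectHits(hits)
  )
}

#' Overlay interval scores onto a binned genome
#'
#' Each bin receives the sum of the scores of every interval overlapping it.
#' The full score of an interval is added to every bin it touches — no
#' length proration — matching presence-based anchor semantics; set
#' `prorate = TRUE` to weight by the per-bin overlap fraction instead.
#'
#' @param bins A `genome_bins` table from [bin_genome()].
#' @param intervals Data frame with `chrom`, `start`, `end` and a score column.
#' @param column Name of the output column added to `bins`.
#' @param score_col Name of the score column in `intervals`.
#' @param prorate Weight scores by overlap fraction (default `FALSE`).
#' @return `bins` with the new (or incremented) score column.
#' @export
overlay_score <- function(bins, intervals, column, score_col = "score",
                          prorate = FALSE) {
  intervals <- tibble::as_tibble(intervals)
  check_known_chroms(bins, intervals)
  vals <- rep(0, nrow(bins))
  if (nrow(intervals) > 0) {
    h <- bin_interval_hits(bins, intervals)
    if (nrow(h) > 0) {
      w <- intervals[[score_col]][h$iv]
      if (prorate) {
        ov <- pmin(bins$end[h$bin], intervals$end[h$iv]) -
          pmax(bins$start[h$bin], intervals$start[h$iv])
        w <- w * ov / (intervals$end[h$iv] - intervals$start[h$iv])
      }
      agg <- rowsum(w, group = h$bin)
      vals[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  bins[[column]] <- vals
  restore_bins(bins, bins)
}

#' Overlay feature spans onto a binned genome, capped per bin
#'
#' Each bin receives the summed overlap in bp of the supplied feature
#' intervals, capped at `cap` (default the bin width) so features that recur
#' at a location — e.g. promoters or enhancers shared by several genes —
#' cannot count more than once per bin.
#'
#' @inheritParams overlay_score
#' @param cap Per-bin ceiling in bp; defaults to the bin width.
#' @return `bins` with the new span column (integer bp, `0..cap`).
#' @export
overlay_span <- function(bins, intervals, column, cap = NULL) {
  intervals <- tibble::as_tibble(intervals)
  check_known_chroms(bins, intervals)
  cap <- cap %||% bin_width_of(bins)
  vals <- rep(0, nrow(bins))
  if (nrow(intervals) > 0) {
    h <- bin_interval_hits(bins, intervals)
    if (nrow(h) > 0) {
      ov <- pmin(bins$end[h$bin], intervals$end[h$iv]) -
        pmax(bins$start[h$bin], intervals$start[h$iv])
      agg <- rowsum(ov, group = h$bin)
      vals[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  bins[[column]] <- pmin(vals, cap)
  restore_bins(bins, bins)
}

#' Interaction anchor strength per bin
#'
#' Sums loop scores into every bin overlapped by either anchor, regardless
#' of which anchor the overlap comes from; a loop whose two anchors hit the
#' same bin contributes twice there unless `dedupe_anchors = TRUE`.
#'
#' @param bins A `genome_bins` table.
#' @param loops A [loop_set()].
#' @param column Output column name (default `"anchor_strength"`).
#' @param q_max Optional FDR filter applied before summation.
#' @param dedupe_anchors Count a loop at most once per bin (default `FALSE`).
#' @return `bins` with the anchor-strength column added.
#' @export
anchor_strength <- function(bins, loops, column = "anchor_strength",
                            q_max = NULL, dedupe_anchors = FALSE) {
  if (!is.null(q_max)) loops <- filter_loops_q(loops, q_max)
  anchors <- dplyr::bind_rows(
    tibble::tibble(
      chrom = loops$chrom1, start = loops$start1, end = loops$end1,
      score = loops$score, loop = seq_len(nrow(loops))
    ),
    tibble::tibble(
      chrom = loops$chrom2, start = loops$start2, end = loops$end2,
      score = loops$score, loop = seq_len(nrow(loops))
    )
  )
  vals <- rep(0, nrow(bins))
  if (nrow(anchors) > 0) {
    check_known_chroms(bins, anchors)
    h <- bin_interval_hits(bins, anchors)
    if (nrow(h) > 0) {
      if (dedupe_anchors) {
        h$loop <- anchors$loop[h$iv]
        h <- dplyr::distinct(h, .data$bin, .data$loop, .keep_all = TRUE)
      }
      agg <- rowsum(anchors$score[h$iv], group = h$bin)
      vals[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  bins[[column]] <- vals
  restore_bins(bins, bins)
}
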