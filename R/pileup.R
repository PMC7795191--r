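#' Pile-up matrices: loci x offset bins with masking
#'
#' The backbone container of every aligned analysis: one row per locus
#' (midpoint, TAD border, stacked TAD), one column per fixed-width offset
#' bin, with a logical mask marking cells that must never enter a summary
#' (chromosome edges, positions past a TAD midpoint). All summaries ignore
#' masked cells.
#'
#' @param values Numeric matrix, loci x offset bins.
#' @param offsets Left edge (bp, signed) of each offset bin relative to the
#'   alignment origin.
#' @param bin Offset-bin width in bp.
#' @param rows Tibble of per-locus metadata (one row per matrix row).
#' @param mask Logical matrix, `TRUE` = masked; defaults to none.
#' @return A `pileup_matrix` object.
#' @export
pileup_matrix <- function(values, offsets, bin, rows = NULL, mask = NULL) {
  assert_that(is.matrix(values), "`values` must be a matrix")
  mask <- mask %||% matrix(FALSE, nrow(values), ncol(values))
  assert_that(all(dim(mask) == dim(values)), "mask/values dimension mismatch")
  assert_that(length(offsets) == ncol(values), "one offset per column required")
  rows <- rows %||% tibble::tibble(.rows = nrow(values))
  structure(
    list(values = values, mask = mask, offsets = offsets, bin = bin, rows = rows),
    class = "pileup_matrix"
  )
}

#' @export
print.pileup_matrix <- function(x, ...) {
  cat(sprintf(
    "<pileup_matrix> %d loci x %d offset bins (%s bp), %.1f%% masked\n",
    nrow(x$values), ncol(x$values), fmt_num(x$bin), 100 * mean(x$mask)
  ))
  invisible(x)
}

#' Column means of a pile-up (masked cells excluded)
#'
#' @param pileup A [pileup_matrix()].
#' @return Tibble with `offset`, `mean` and `n` (unmasked loci per column).
#' @export
pileup_colmeans <- function(pileup) {
  v <- pileup$values
  v[pileup$mask] <- NA
  tibble::tibble(
    offset = pileup$offsets,
    mean = colMeans(v, na.rm = TRUE),
    n = colSums(!pileup$mask)
  )
}

#' Row means of a pile-up in blocks of consecutive loci
#'
#' @param pileup A [pileup_matrix()].
#' @param k Loci per block (default 5, the 5-TADs-per-point convention).
#' @return Tibble with `block`, `row_from`, `row_to`, `mean`.
#' @export
pileup_rowmeans <- function(pileup, k = 5) {
  v <- pileup$values
  v[pileup$mask] <- NA
  rm_ <- rowMeans(v, na.rm = TRUE)
  blk <- (seq_along(rm_) - 1L) %/% k + 1L
  tibble::tibble(
    block = unique(blk),
    row_from = as.integer(tapply(seq_along(rm_), blk, min)),
    row_to = as.integer(tapply(seq_along(rm_), blk, max)),
    mean = as.numeric(tapply(rm_, blk, mean, na.rm = TRUE))
  )
}

#' Average a column-mean profile in blocks of consecutive bins
#'
#' @param colmeans Output of [pileup_colmeans()] (or any tibble with
#'   `offset` and `mean`).
#' @param k Bins per block (default 5: 5 kb spans from 1 kb bins).
#' @return Tibble with `offset` (block left edge) and `mean`.
#' @export
summarize_profile <- function(colmeans, k = 5) {
  blk <- (seq_len(nrow(colmeans)) - 1L) %/% k
  tibble::tibble(
    offset = as.numeric(tapply(colmeans$offset, blk, min)),
    mean = as.numeric(tapply(colmeans$mean, blk, mean, na.rm = TRUE))
  )
}

#' Reverse the orientation of selected pile-up rows
#'
#' Reverses values and mask of the given rows left-to-right. Applying the
#' same flip twice restores the original matrix exactly (involution).
#'
#' @param pileup A [pileup_matrix()].
#' @param rows Integer or logical row index (default: all rows).
#' @return The flipped `pileup_matrix`.
#' @export
flip_pileup_rows <- function(pileup, rows = seq_len(nrow(pileup$values))) {
  rev_cols <- rev(seq_len(ncol(pileup$values)))
  pileup$values[rows, ] <- pileup$values[rows, rev_cols, drop = FALSE]
  pileup$mask[rows, ] <- pileup$mask[rows, rev_cols, drop = FALSE]
  pileup
}

# per-chromosome value vector lookup for a genome_bins column
bins_signal_index <- function(table, column) {
  w <- bin_width_of(table)
  sp <- split(table[[column]], table$chrom)
  list(values = sp, width = w)
}

# read signal at arbitrary bin indices (1-based); out of range -> NA
signal_at_idx <- function(idx_store, chrom, bin_idx) {
  v <- idx_store$values[[chrom]]
  out <- rep(NA_real_, length(bin_idx))
  ok <- bin_idx >= 1 & bin_idx <= length(v)
  out[ok] <- v[bin_idx[ok]]
  out
}

#' Align a binned-genome signal at a set of midpoints
#'
#' Extracts, for each locus, the signal column of the binned genome in a
#' window of `flank` bp either side of the locus, producing a
#' [pileup_matrix()] whose offset-0 column is the bin containing the
#' midpoint. Loci running off a chromosome end have the out-of-range
#' columns masked.
#'
#' @param table A `genome_bins` table carrying the signal column.
#' @param column Signal column name.
#' @param midpoints Tibble with `chrom` and `pos` (bp).
#' @param flank Half-window in bp (default 1 Mb).
#' @return A `pileup_matrix` (use [pileup_colmeans()] and
#'   [summarize_profile()] for the 5 kb column summary).
#' @export
align_midpoints <- function(table, column, midpoints, flank = 1e6) {
  assert_that(nrow(midpoints) > 0, "empty midpoint list")
  w <- bin_width_of(table)
  K <- as.integer(flank / w)
  store <- bins_signal_index(table, column)
  offs <- seq(-K, K - 1L) * w
  n <- nrow(midpoints)
  vals <- matrix(NA_real_, n, 2L * K)
  for (r in seq_len(n)) {
    center <- floor(midpoints$pos[r] / w) + 1L
    vals[r, ] <- signal_at_idx(store, midpoints$chrom[r], center + seq(-K, K - 1L))
  }
  mask <- is.na(vals)
  vals[mask] <- 0
  pileup_matrix(vals, offs, w,
    rows = tibble::as_tibble(midpoints), mask = mask)
}

#' Per-offset count of loci covered by a TAD
#'
#' For each offset bin around each locus, counts how many loci have that
#' position inside a TAD — the "number of overlapping TAD domains" track of
#' midpoint-aligned analyses.
#'
#' @param midpoints Tibble with `chrom`, `pos`.
#' @param tads A [tad_set()].
#' @param flank Half-window in bp.
#' @param bin Offset bin width in bp.
#' @return Tibble with `offset` and `count` (in `0..n_loci`).
#' @export
tad_overlap_profile <- function(midpoints, tads, flank = 1e6, bin = 1000) {
  K <- as.integer(flank / bin)
  offs <- (seq(-K, K - 1L) + 0.5) * bin
  counts <- rep(0L, 2L * K)
  for (ch in unique(midpoints$chrom)) {
    td <- tads[tads$chrom == ch, , drop = FALSE]
    pos0 <- midpoints$pos[midpoints$chrom == ch]
    if (nrow(td) == 0 || length(pos0) == 0) next
    starts <- sort(td$start)
    ends <- td$end[order(td$start)]
    for (p in pos0) {
      pos <- p + offs
      idx <- findInterval(pos, starts)
      covered <- idx > 0 & pos < ends[pmax(1, idx)]
      counts <- counts + covered
    }
  }
  tibble::tibble(offset = offs - 0.5 * bin, count = as.integer(counts))
}

#' Orient DiffTADs by regulated-gene directionality
#'
#' Assigns each TAD an orientation from the length-normalized sum of
#' strand-directional spans of its significantly regulated,
#' direction-consistent genes (q below `q_max`, log2FC sign matching
#' `direction`): plus-strand genes contribute +length, minus-strand genes
#' -length. TADs with no qualifying gene default to forward and are
#' flagged.
#'
#' @param tads A [tad_set()].
#' @param expression Expression table with `chrom`, `start`, `end`,
#'   `strand`, `log2fc`, `q`.
#' @param direction `"up"` or `"down"` (sign of log2FC that qualifies).
#' @param q_max Significance cutoff (default 0.05).
#' @return `tads` with `orientation` (+1/-1) and `default_orientation`
#'   columns.
#' @export
orient_difftads <- function(tads, expression, direction = c("up", "down"),
                            q_max = 0.05) {
  direction <- match.arg(direction)
  assert_that(nrow(tads) > 0, "empty TAD list")
  sgn <- if (direction == "up") 1 else -1
  genes <- expression[
    !is.na(expression$q) & expression$q < q_max &
      sign(expression$log2fc) == sgn, ,
    drop = FALSE
  ]
  ori <- rep(1, nrow(tads))
  flagged <- rep(TRUE, nrow(tads))
  if (nrow(genes) > 0) {
    gg <- intervals_to_granges(genes)
    tg <- intervals_to_granges(tads)
    h <- GenomicRanges::findOverlaps(tg, gg)
    qh <- S4Vectors::queryHits(h)
    sh <- S4Vectors::subjectHits(h)
    span <- (genes$end[sh] - genes$start[sh]) *
      ifelse(genes$strand[sh] == "+", 1, -1)
    agg <- rowsum(span, qh)
    tid <- as.integer(rownames(agg))
    net <- agg[, 1] / ((tads$end[tid] - tads$start[tid]) / 1000)
    ori[tid] <- ifelse(net >= 0, 1, -1)
    flagged[tid] <- FALSE
  }
  out <- tibble::as_tibble(tads)
  out$orientation <- ori
  out$default_orientation <- flagged
  out
}

#' Border-aligned pile-ups of oriented DiffTADs
#'
#' Builds left- and right-border aligned pile-up matrices of a
#' binned-genome signal for oriented TADs. Reverse-oriented TADs are
#' coordinate-flipped before alignment (their physical right border plays
#' the left role and the signal is read mirrored). Rows are sorted by TAD
#' length (shortest first) and cells past each TAD's own midpoint are
#' masked so the two borders never average together.
#'
#' @param tads Oriented TADs from [orient_difftads()] (or a [tad_set()];
#'   orientation then defaults to forward).
#' @param table A `genome_bins` table with the signal column.
#' @param column Signal column name.
#' @param flank Half-window in bp around each border (default 500 kb).
#' @return List with `left` and `right` [pileup_matrix()]s.
#' @export
align_tad_borders <- function(tads, table, column, flank = 5e5) {
  assert_that(nrow(tads) > 0, "empty TAD list")
  if (!"orientation" %in% names(tads)) tads$orientation <- 1
  w <- bin_width_of(table)
  K <- as.integer(flank / w)
  offs <- seq(-K, K - 1L) * w
  store <- bins_signal_index(table, column)
  tads <- dplyr::arrange(tibble::as_tibble(tads), .data$end - .data$start)
  len <- tads$end - tads$start
  n <- nrow(tads)
  build <- function(side) {
    vals <- matrix(NA_real_, n, 2L * K)
    mask <- matrix(FALSE, n, 2L * K)
    for (r in seq_len(n)) {
      o <- tads$orientation[r]
      origin <- if (side == "left") {
        if (o > 0) tads$start[r] else tads$end[r]
      } else {
        if (o > 0) tads$end[r] else tads$start[r]
      }
      # genomic position of each offset bin center, read along orientation
      pos <- origin + o * (offs + w / 2)
      idx <- floor(pos / w) + 1L
      vals[r, ] <- signal_at_idx(store, tads$chrom[r], idx)
      inside_past_mid <- if (side == "left") {
        offs + w / 2 > len[r] / 2
      } else {
        offs + w / 2 < -len[r] / 2
      }
      mask[r, ] <- is.na(vals[r, ]) | inside_past_mid
    }
    vals[is.na(vals)] <- 0
    pileup_matrix(vals, offs, w, rows = tads, mask = mask)
  }
  list(left = build("left"), right = build("right"))
}

#' Stack same-size TADs sorted by an attribute
#'
#' Selects `n` TADs whose size matches `size` within `size_tol`, extracts
#' each attribute across every TAD at the binned-genome resolution, sorts
#' the rows by decreasing mean of `sort_attr`, and reports 5-TAD-binned row
#' means together with the Pearson correlation (and R^2) between the binned
#' sort attribute and each other attribute — the "which features sort
#' together with interaction strength" readout.
#'
#' @param tads A [tad_set()].
#' @param table A `genome_bins` table carrying all attribute columns.
#' @param attrs Character vector of attribute columns to compare.
#' @param sort_attr Sorting attribute column (default `anchor_strength`).
#' @param size Target TAD size in bp (default 480 kb).
#' @param n Number of TADs to stack (default 200).
#' @param size_tol Size tolerance in bp (default one 40 kb bin).
#' @param row_block TADs per row-mean point (default 5).
#' @return A `tad_stack`: list with `pileups` (named per attribute),
#'   `row_means` (binned means per attribute) and `correlations`
#'   (`attr`, `r`, `r_squared`).
#' @export
stack_same_size <- function(tads, table, attrs, sort_attr = "anchor_strength",
                            size = 480000, n = 200, size_tol = 40000,
                            row_block = 5) {
  len <- tads$end - tads$start
  sel <- which(abs(len - size) <= size_tol)
  assert_that(length(sel) >= n,
    sprintf("need %d TADs of size %s +/- %s bp, found %d",
      n, fmt_num(size), fmt_num(size_tol), length(sel)))
  sel <- sel[seq_len(n)]
  sub <- tibble::as_tibble(tads)[sel, , drop = FALSE]
  w <- bin_width_of(table)
  ncol_ <- as.integer(round(size / w))
  extract <- function(column) {
    store <- bins_signal_index(table, column)
    vals <- matrix(NA_real_, n, ncol_)
    for (r in seq_len(n)) {
      idx <- floor(sub$start[r] / w) + seq_len(ncol_)
      vals[r, ] <- signal_at_idx(store, sub$chrom[r], idx)
    }
    mask <- is.na(vals)
    vals[mask] <- 0
    pileup_matrix(vals, (seq_len(ncol_) - 1L) * w, w, rows = sub, mask = mask)
  }
  sort_pu <- extract(sort_attr)
  key <- rowMeans(sort_pu$values)
  ord <- order(-key)
  reorder_pu <- function(p) {
    p$values <- p$values[ord, , drop = FALSE]
    p$mask <- p$mask[ord, , drop = FALSE]
    p$rows <- p$rows[ord, , drop = FALSE]
    p
  }
  sort_pu <- reorder_pu(sort_pu)
  pileups <- list()
  pileups[[sort_attr]] <- sort_pu
  for (a in setdiff(attrs, sort_attr)) pileups[[a]] <- reorder_pu(extract(a))
  sort_binned <- pileup_rowmeans(sort_pu, k = row_block)$mean
  row_means <- tibble::tibble(block = seq_along(sort_binned))
  correlations <- list()
  for (a in names(pileups)) {
    m <- pileup_rowmeans(pileups[[a]], k = row_block)$mean
    row_means[[a]] <- m
    if (a != sort_attr) {
      r <- cor(sort_binned, m)
      correlations[[a]] <- tibble::tibble(attr = a, r = r, r_squared = r^2)
    }
  }
  structure(
    list(
      pileups = pileups, row_means = row_means,
      correlations = dplyr::bind_rows(correlations),
      sort_attr = sort_attr
    ),
    class = "tad_stack"
  )
}

#' Split all TADs in half and align by left and right borders
#'
#' Every TAD contributes its left half to a left-aligned block and its
#' right half to a right-aligned block (offset 0 at the border, growing
#' inward), leaving masked gaps where a TAD is shorter than the widest one.
#' TADs longer than `max_unsplit` contribute only their outer
#' `max_unsplit / 2` per side, removing the middle. Rows are sorted by TAD
#' length.
#'
#' @param tads A [tad_set()].
#' @param table A `genome_bins` table.
#' @param column Signal column name.
#' @param max_unsplit TADs longer than this have their middle removed
#'   (default 2 Mb).
#' @param col_block Bins per column-mean point (default 5).
#' @param row_block TADs per row-mean point (default 5).
#' @return A list with `left`/`right` [pileup_matrix()]s plus `col_means`
#'   and `row_means` tibbles for both sides.
#' @export
split_align_all <- function(tads, table, column, max_unsplit = 2e6,
                            col_block = 5, row_block = 5) {
  w <- bin_width_of(table)
  tads <- dplyr::arrange(tibble::as_tibble(tads), .data$end - .data$start)
  len <- tads$end - tads$start
  half <- pmin(len / 2, max_unsplit / 2)
  half_bins <- pmax(1L, as.integer(floor(half / w)))
  width <- max(half_bins)
  n <- nrow(tads)
  store <- bins_signal_index(table, column)
  vals_l <- vals_r <- matrix(0, n, width)
  mask_l <- mask_r <- matrix(TRUE, n, width)
  for (r in seq_len(n)) {
    hb <- half_bins[r]
    li <- floor(tads$start[r] / w) + seq_len(hb)
    vl <- signal_at_idx(store, tads$chrom[r], li)
    vals_l[r, seq_len(hb)] <- ifelse(is.na(vl), 0, vl)
    mask_l[r, seq_len(hb)] <- is.na(vl)
    ri <- floor(tads$end[r] / w) + 1L - seq_len(hb)
    vr <- signal_at_idx(store, tads$chrom[r], ri)
    vals_r[r, seq_len(hb)] <- ifelse(is.na(vr), 0, vr)
    mask_r[r, seq_len(hb)] <- is.na(vr)
  }
  offs <- (seq_len(width) - 1L) * w
  left <- pileup_matrix(vals_l, offs, w, rows = tads, mask = mask_l)
  right <- pileup_matrix(vals_r, offs, w, rows = tads, mask = mask_r)
  list(
    left = left, right = right,
    col_means = list(
      left = summarize_profile(pileup_colmeans(left), k = col_block),
      right = summarize_profile(pileup_colmeans(right), k = col_block)
    ),
    row_means = list(
      left = pileup_rowmeans(left, k = row_block),
      right = pileup_rowmeans(right, k = row_block)
    )
  )
}
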