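#' Directionality index of a binned contact matrix
#'
#' For each bin, sums the contacts to the `window` bp upstream (`A`) and
#' downstream (`B`) and forms the signed chi-square-like directionality
#' index
#' \deqn{DI = \frac{B-A}{|B-A|}\left(\frac{(A-E)^2}{E} + \frac{(B-E)^2}{E}\right),
#'   \quad E = (A+B)/2,}
#' which is strongly positive just downstream of a domain border and
#' strongly negative just upstream of one. Bins near the chromosome edge use
#' the truncated window and keep their DI (set `mask_edges = TRUE` to NA
#' them instead). `A = B` or `E = 0` give `DI = 0`.
#'
#' @param mat Square symmetric non-negative contact matrix at `bin` bp.
#' @param bin Bin width in bp (default 40 kb).
#' @param window One-sided window in bp (default 2 Mb).
#' @param chrom Chromosome label stored on the track.
#' @param mask_edges Mask bins whose window is truncated (default `FALSE`).
#' @return A `di_track` tibble: `chrom`, `start`, `end`, `A`, `B`, `E`, `DI`.
#' @export
directionality_index <- function(mat, bin = 40000, window = 2e6,
                                 chrom = "chr1", mask_edges = FALSE) {
  assert_that(is.matrix(mat) && nrow(mat) == ncol(mat),
    "`mat` must be a square matrix")
  assert_that(all(mat >= 0), "`mat` must be non-negative")
  n <- nrow(mat)
  w <- max(1L, as.integer(window / bin))
  A <- B <- numeric(n)
  for (i in seq_len(n)) {
    up <- seq.int(max(1L, i - w), i - 1L)
    dn <- seq.int(i + 1L, min(n, i + w))
    A[i] <- if (i > 1L) sum(mat[i, up]) else 0
    B[i] <- if (i < n) sum(mat[i, dn]) else 0
  }
  E <- (A + B) / 2
  DI <- ifelse(A == B | E == 0, 0,
    sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  )
  if (mask_edges) {
    edge <- seq_len(n) <= w | seq_len(n) > n - w
    DI[edge] <- NA_real_
  }
  structure(
    tibble::tibble(
      chrom = chrom,
      start = (seq_len(n) - 1) * bin,
      end = seq_len(n) * bin,
      A = A, B = B, E = E, DI = DI
    ),
    bin = bin, window = window,
    class = c("di_track", class(tibble::tibble()))
  )
}

# maximal runs of identical sign over the non-zero entries of s, recorded as
# (sign, first bin index, last bin index)
sign_runs <- function(s) {
  nz <- which(s != 0)
  if (length(nz) == 0) {
    return(tibble::tibble(sign = integer(), from = integer(), to = integer(), n = integer()))
  }
  # a run breaks when the sign changes; zero gaps between same-sign bins are bridged
  grp <- cumsum(c(TRUE, s[nz[-1]] != s[nz[-length(nz)]]))
  tibble::tibble(
    sign = as.integer(tapply(s[nz], grp, function(x) x[1])),
    from = as.integer(tapply(nz, grp, min)),
    to = as.integer(tapply(nz, grp, max)),
    n = as.integer(tapply(nz, grp, length))
  )
}

#' Call TADs from a directionality-index track
#'
#' Deterministic run-segmentation of the DI sign: a TAD opens at the first
#' bin of a sustained positive run (downstream-biased contacts, i.e. just
#' inside a left border) and closes at the last bin of the sustained
#' negative run(s) that follow, before the next positive run. Bins with
#' `|DI|` below the noise floor are treated as zero and bridge runs of equal
#' sign. Domains shorter than `min_length` are dropped.
#'
#' @param di A `di_track` from [directionality_index()].
#' @param sustain Minimum run length in bins for a run to count (default 2).
#' @param noise_floor Absolute-DI floor; default `0.2 * median(|DI|)` over
#'   non-zero bins.
#' @param min_length Minimum TAD length in bp (default 120 kb = 3 bins).
#' @param condition Condition label stored on the result.
#' @return A `tad_set` tibble (`chrom`, `start`, `end`), sorted and
#'   non-overlapping.
#' @export
call_tads <- function(di, sustain = 2, noise_floor = NULL, min_length = 120000,
                      condition = NA_character_) {
  assert_that(nrow(di) > 0, "empty DI track")
  bin <- attr(di, "bin") %||% (di$end[1] - di$start[1])
  out <- dplyr::group_modify(dplyr::group_by(di, .data$chrom), function(d, key) {
    x <- d$DI
    x[is.na(x)] <- 0
    floor_ <- noise_floor %||% (0.2 * median(abs(x[x != 0])))
    if (!is.finite(floor_)) floor_ <- 0
    s <- sign(x)
    s[abs(x) < floor_] <- 0L
    runs <- sign_runs(s)
    runs <- runs[runs$n >= sustain, , drop = FALSE]
    starts <- ends <- integer(0)
    open_from <- NA_integer_
    close_to <- NA_integer_
    for (k in seq_len(nrow(runs))) {
      if (runs$sign[k] > 0) {
        if (!is.na(open_from) && !is.na(close_to)) {
          starts <- c(starts, open_from); ends <- c(ends, close_to)
          open_from <- NA_integer_; close_to <- NA_integer_
        }
        if (is.na(open_from)) open_from <- runs$from[k]
      } else if (!is.na(open_from)) {
        close_to <- runs$to[k]
      }
    }
    if (!is.na(open_from) && !is.na(close_to)) {
      starts <- c(starts, open_from); ends <- c(ends, close_to)
    }
    tb <- tibble::tibble(
      start = d$start[starts],
      end = d$end[ends]
    )
    tb[tb$end - tb$start >= min_length, , drop = FALSE]
  })
  out <- dplyr::ungroup(out)[, c("chrom", "start", "end")]
  tad_set(out, condition = condition)
}

#' Construct a TAD set
#'
#' @param domains Data frame with `chrom`, `start`, `end` (bp, 0-based
#'   half-open); must be non-overlapping within a chromosome.
#' @param condition Condition label.
#' @return A sorted `tad_set` tibble.
#' @export
tad_set <- function(domains, condition = NA_character_) {
  domains <- tibble::as_tibble(domains)[, c("chrom", "start", "end")]
  domains <- dplyr::arrange(domains, .data$chrom, .data$start)
  bad <- dplyr::group_by(domains, .data$chrom)
  bad <- dplyr::summarise(bad, ov = any(.data$start[-1] < .data$end[-length(.data$end)]))
  assert_that(!any(bad$ov), "TADs overlap within a chromosome")
  structure(domains,
    condition = condition,
    class = c("tad_set", class(tibble::tibble()))
  )
}

tad_borders <- function(tads) {
  dplyr::distinct(tibble::tibble(
    chrom = rep(tads$chrom, 2),
    pos = c(tads$start, tads$end)
  ))
}

#' Compare TAD borders between two conditions
#'
#' For every border of set A the distance to the closest border of set B on
#' the same chromosome is computed (A-to-B, as a directional comparison;
#' ties broken toward the lower coordinate). A border counts as changed when
#' that distance is at least `changed_threshold`. Summary statistics
#' (percent changed, mean/min/max shift) are reported over the changed
#' borders, together with per-set domain counts and size summaries.
#'
#' @param tads_a,tads_b Two [tad_set()]s (non-empty).
#' @param changed_threshold Minimum shift in bp to call a border changed
#'   (default one 40 kb bin).
#' @return A `border_shift` object; `glance()` gives the one-row summary,
#'   `tidy()` the per-border distances.
#' @export
compare_tads <- function(tads_a, tads_b, changed_threshold = 40000) {
  assert_that(nrow(tads_a) > 0 && nrow(tads_b) > 0, "empty TAD set")
  ba <- tad_borders(tads_a)
  bb <- tad_borders(tads_b)
  nearest_dist <- function(pos, ref) {
    if (length(ref) == 0) {
      return(rep(Inf, length(pos)))
    }
    ref <- sort(ref)
    vapply(pos, function(p) {
      d <- abs(ref - p)
      i <- which(d == min(d))
      d[i[1]] # ties toward the lower coordinate
    }, numeric(1))
  }
  ord <- order(ba$chrom, ba$pos)
  per_border <- tibble::tibble(chrom = ba$chrom[ord], pos = ba$pos[ord])
  per_border$dist <- unlist(lapply(
    split(seq_len(nrow(per_border)), per_border$chrom),
    function(idx) {
      ch <- per_border$chrom[idx[1]]
      nearest_dist(per_border$pos[idx], bb$pos[bb$chrom == ch])
    }
  ), use.names = FALSE)
  changed <- per_border$dist >= changed_threshold
  shifts <- per_border$dist[changed & is.finite(per_border$dist)]
  stats <- tibble::tibble(
    n_borders = nrow(per_border),
    pct_changed = 100 * mean(changed),
    mean_shift = if (length(shifts)) mean(shifts) else 0,
    min_shift = if (length(shifts)) min(shifts) else 0,
    max_shift = if (length(shifts)) max(shifts) else 0,
    n_tads_a = nrow(tads_a),
    n_tads_b = nrow(tads_b),
    mean_size_a = mean(tads_a$end - tads_a$start),
    mean_size_b = mean(tads_b$end - tads_b$start)
  )
  structure(
    list(stats = stats, per_border = per_border,
      changed_threshold = changed_threshold),
    class = "border_shift"
  )
}

#' @export
print.border_shift <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<border_shift> %d borders; %.2f%% changed (>= %s bp), mean %.0f bp [%.0f, %.0f]\n",
    s$n_borders, s$pct_changed, fmt_num(x$changed_threshold),
    s$mean_shift, s$min_shift, s$max_shift
  ))
  invisible(x)
}
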