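#' Chromatin loop sets
#'
#' A loop set is a tibble of BEDPE-style interaction records — two anchors,
#' an interaction score and an FDR q value — with the condition label and
#' library size (`total_valid_pairs`) attached as attributes. It is the
#' currency passed between every Hi-C/HiChIP stage of the pipeline.
#'
#' Intra-chromosomal records are stored with anchor 1 upstream of anchor 2;
#' the constructor swaps anchors where needed and validates coordinates
#' (0-based half-open).
#'
#' @param records A data frame with columns `chrom1,start1,end1,chrom2,
#'   start2,end2,score` and optionally `name`, `q`, `pets`.
#' @param condition Condition label (e.g. `"ESC"`).
#' @param total_valid_pairs Library size used by [normalize_conditions()];
#'   defaults to `sum(score)`.
#' @return A `loop_set` tibble.
#' @export
loop_set <- function(records, condition = NA_character_, total_valid_pairs = NULL) {
  records <- tibble::as_tibble(records)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "score")
  assert_that(all(need %in% names(records)),
    paste("loop records need columns:", paste(need, collapse = ", ")))
  assert_that(all(records$start1 < records$end1) && all(records$start2 < records$end2),
    "anchor intervals must satisfy start < end")
  if (!"q" %in% names(records)) records$q <- NA_real_
  qq <- records$q[!is.na(records$q)]
  assert_that(all(qq >= 0 & qq <= 1), "q values must lie in [0, 1]")
  assert_that(all(records$score >= 0), "loop scores must be non-negative")
  # order anchors on intra-chromosomal records
  swap <- records$chrom1 == records$chrom2 & records$start1 > records$start2
  if (any(swap)) {
    tmp <- records[swap, c("chrom1", "start1", "end1")]
    records[swap, c("chrom1", "start1", "end1")] <-
      records[swap, c("chrom2", "start2", "end2")]
    records[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  structure(records,
    condition = condition,
    total_valid_pairs = total_valid_pairs %||% sum(records$score),
    class = c("loop_set", class(tibble::tibble()))
  )
}

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf(
    "<loop_set> %d loops, condition=%s, total_valid_pairs=%s\n",
    nrow(x), attr(x, "condition"), fmt_num(attr(x, "total_valid_pairs"))
  ))
  NextMethod()
}

loop_condition <- function(loops) attr(loops, "condition")

loop_mass <- function(loops) {
  m <- attr(loops, "total_valid_pairs")
  if (is.null(m)) sum(loops$score) else m
}

#' Filter a loop set by FDR q
#'
#' @param loops A [loop_set()].
#' @param q_max Keep loops with `q < q_max`.
#' @return A filtered `loop_set` (metadata preserved).
#' @export
filter_loops_q <- function(loops, q_max) {
  keep <- !is.na(loops$q) & loops$q < q_max
  out <- loops[keep, , drop = FALSE]
  attr(out, "condition") <- attr(loops, "condition")
  attr(out, "total_valid_pairs") <- attr(loops, "total_valid_pairs")
  class(out) <- class(loops)
  out
}

#' Normalize two loop sets to a common library size
#'
#' Scores of the larger-mass set are scaled by `min(mass) / its mass`, so
#' the two conditions become directly comparable while within-set ratios are
#' preserved. The smaller set is returned unchanged. Linear scaling (rather
#' than subsampling) keeps the operation deterministic; see
#' [subsample_loops()] for the stochastic alternative.
#'
#' @param loops_a,loops_b Two [loop_set()]s carrying `total_valid_pairs`.
#' @return A list with elements `a` and `b` (scaled loop sets).
#' @export
normalize_conditions <- function(loops_a, loops_b) {
  ma <- loop_mass(loops_a)
  mb <- loop_mass(loops_b)
  assert_that(ma > 0 && mb > 0, "both loop sets must have positive total mass")
  scale_set <- function(loops, f, new_mass) {
    loops$score <- loops$score * f
    attr(loops, "total_valid_pairs") <- new_mass
    loops
  }
  mmin <- min(ma, mb)
  list(
    a = scale_set(loops_a, mmin / ma, mmin),
    b = scale_set(loops_b, mmin / mb, mmin)
  )
}

#' Randomly subsample a loop set to a target mass
#'
#' Thins integer-like scores binomially so the expected total equals
#' `target_mass`; offered as a sensitivity check next to the deterministic
#' [normalize_conditions()].
#'
#' @param loops A [loop_set()].
#' @param target_mass Target total score mass (must not exceed current mass).
#' @param seed Integer seed.
#' @return A `loop_set` with thinned scores.
#' @export
subsample_loops <- function(loops, target_mass, seed = 1L) {
  m <- loop_mass(loops)
  assert_that(target_mass <= m, "target mass exceeds current mass")
  p <- target_mass / m
  with_stream(seed, "subsample_loops", {
    loops$score <- rbinom(nrow(loops), size = round(loops$score), prob = p)
  })
  attr(loops, "total_valid_pairs") <- sum(loops$score)
  loops
}

loop_midpoints <- function(loops) {
  a1 <- (loops$start1 + loops$end1) / 2
  a2 <- (loops$start2 + loops$end2) / 2
  (a1 + a2) / 2
}
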