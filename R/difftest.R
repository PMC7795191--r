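#' Hierarchical binned interaction grid
#'
#' Accumulates loop scores onto a fine-binned genome scaffold (each loop is
#' assigned to the single fine-bin pair containing its two anchor
#' midpoints), then groups fine-bin pairs into coarse cells so that every
#' coarse cell holds the vector of its (coarse/fine)^2 fine-pair values —
#' e.g. 100 values per 1 Mb x 1 Mb cell from its 100 kb combinations.
#' Diagonal coarse cells hold the upper-triangle combinations only, so no
#' fine pair is counted twice.
#'
#' @param loops A [loop_set()].
#' @param chrom_sizes Chromosome sizes (data frame or named vector).
#' @param fine Fine bin width in bp (e.g. 100 kb genome-wide, 1 kb locus).
#' @param coarse Coarse cell width in bp; must be a multiple of `fine`.
#' @param scope `"intra"` (within-chromosome, default), `"inter"`
#'   (chromosome pairs) or `"region"` (one window, see `region`).
#' @param region For `scope = "region"`: `list(chrom =, start =, end =)`.
#' @return An `interaction_grid` object.
#' @export
hierarchical_grid <- function(loops, chrom_sizes, fine, coarse,
                              scope = c("intra", "inter", "region"),
                              region = NULL) {
  scope <- match.arg(scope)
  assert_that(coarse %% fine == 0, "`coarse` must be a multiple of `fine`")
  cs <- as_chrom_sizes(chrom_sizes)
  mid1 <- (loops$start1 + loops$end1) / 2
  mid2 <- (loops$start2 + loops$end2) / 2
  blocks <- list()
  if (scope == "region") {
    assert_that(!is.null(region), "`region` is required for scope = 'region'")
    keep <- loops$chrom1 == region$chrom & loops$chrom2 == region$chrom &
      mid1 >= region$start & mid1 < region$end &
      mid2 >= region$start & mid2 < region$end
    n <- ceiling((region$end - region$start) / fine)
    mat <- matrix(0, n, n)
    if (any(keep)) {
      i <- floor((mid1[keep] - region$start) / fine) + 1
      j <- floor((mid2[keep] - region$start) / fine) + 1
      lo <- pmin(i, j); hi <- pmax(i, j)
      for (k in seq_along(lo)) {
        mat[lo[k], hi[k]] <- mat[lo[k], hi[k]] + loops$score[keep][k]
      }
    }
    blocks[[paste0(region$chrom, "|", region$chrom)]] <- list(
      chrom1 = region$chrom, chrom2 = region$chrom,
      offset1 = region$start, offset2 = region$start,
      mat = mat, intra = TRUE
    )
  } else if (scope == "intra") {
    for (r in seq_len(nrow(cs))) {
      ch <- cs$chrom[r]
      n <- ceiling(cs$size[r] / fine)
      mat <- matrix(0, n, n)
      keep <- loops$chrom1 == ch & loops$chrom2 == ch
      if (any(keep)) {
        i <- floor(mid1[keep] / fine) + 1
        j <- floor(mid2[keep] / fine) + 1
        lo <- pmin(i, j); hi <- pmax(i, j)
        sc <- loops$score[keep]
        for (k in seq_along(lo)) mat[lo[k], hi[k]] <- mat[lo[k], hi[k]] + sc[k]
      }
      blocks[[paste0(ch, "|", ch)]] <- list(
        chrom1 = ch, chrom2 = ch, offset1 = 0, offset2 = 0,
        mat = mat, intra = TRUE
      )
    }
  } else {
    combs <- utils::combn(cs$chrom, 2)
    for (k in seq_len(ncol(combs))) {
      ca <- combs[1, k]; cb <- combs[2, k]
      na <- ceiling(cs$size[cs$chrom == ca] / fine)
      nb <- ceiling(cs$size[cs$chrom == cb] / fine)
      mat <- matrix(0, na, nb)
      keep <- (loops$chrom1 == ca & loops$chrom2 == cb) |
        (loops$chrom1 == cb & loops$chrom2 == ca)
      if (any(keep)) {
        flip <- loops$chrom1[keep] == cb
        i <- floor(ifelse(flip, mid2[keep], mid1[keep]) / fine) + 1
        j <- floor(ifelse(flip, mid1[keep], mid2[keep]) / fine) + 1
        sc <- loops$score[keep]
        for (q in seq_along(i)) mat[i[q], j[q]] <- mat[i[q], j[q]] + sc[q]
      }
      blocks[[paste0(ca, "|", cb)]] <- list(
        chrom1 = ca, chrom2 = cb, offset1 = 0, offset2 = 0,
        mat = mat, intra = FALSE
      )
    }
  }
  structure(
    list(
      fine = fine, coarse = coarse, scope = scope, blocks = blocks,
      condition = loop_condition(loops)
    ),
    class = "interaction_grid"
  )
}

grid_geometry_equal <- function(a, b) {
  identical(a$fine, b$fine) && identical(a$coarse, b$coarse) &&
    identical(a$scope, b$scope) && identical(names(a$blocks), names(b$blocks)) &&
    all(vapply(names(a$blocks), function(nm) {
      all(dim(a$blocks[[nm]]$mat) == dim(b$blocks[[nm]]$mat))
    }, logical(1)))
}

# enumerate fine pairs of one block as (i, j, coarse cell key)
block_fine_pairs <- function(block, ratio) {
  n1 <- nrow(block$mat); n2 <- ncol(block$mat)
  if (block$intra) {
    idx <- which(upper.tri(block$mat, diag = TRUE), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(row = seq_len(n1), col = seq_len(n2)))
  }
  ci <- (idx[, 1] - 1L) %/% ratio
  cj <- (idx[, 2] - 1L) %/% ratio
  list(i = idx[, 1], j = idx[, 2], ci = ci, cj = cj)
}

#' Paired t-tests over every coarse cell of two matched grids
#'
#' For each coarse cell the paired differences between the two conditions'
#' fine-pair vectors are tested with a paired t-test (two-sided).
#' `mean_delta` is condition 2 minus condition 1, so a positive delta favors
#' the second grid's condition. Cells whose differences are all zero return
#' p = 1; cells with equal non-zero differences (zero variance) are flagged
#' degenerate. The Bonferroni correction, when enabled, multiplies p by the
#' number of cells with a defined test.
#'
#' @param grid_a,grid_b [hierarchical_grid()]s of identical geometry
#'   (condition 1 and condition 2).
#' @param bonferroni Apply Bonferroni to `p_adj` (default `FALSE`, matching
#'   genome-wide use; enable for locus-scale analyses).
#' @return A `paired_grid_tests` tibble: cell coordinates, `n`, per-condition
#'   means, `mean_delta`, `t`, `df`, `p`, `p_adj`, `favored`, `degenerate`.
#' @export
paired_t_grid <- function(grid_a, grid_b, bonferroni = FALSE) {
  assert_that(grid_geometry_equal(grid_a, grid_b),
    "the two grids have different geometry")
  ratio <- grid_a$coarse / grid_a$fine
  conds <- c(grid_a$condition %||% "A", grid_b$condition %||% "B")
  if (any(is.na(conds))) conds <- c("A", "B")
  out <- list()
  for (nm in names(grid_a$blocks)) {
    ba <- grid_a$blocks[[nm]]
    bb <- grid_b$blocks[[nm]]
    fp <- block_fine_pairs(ba, ratio)
    va <- ba$mat[cbind(fp$i, fp$j)]
    vb <- bb$mat[cbind(fp$i, fp$j)]
    d <- vb - va
    key <- paste0(fp$ci, "_", fp$cj)
    n <- as.vector(rowsum(rep(1, length(d)), key))
    ord_keys <- rownames(rowsum(rep(1, length(d)), key))
    s1 <- as.vector(rowsum(d, key))
    s2 <- as.vector(rowsum(d^2, key))
    sa <- as.vector(rowsum(va, key))
    sb <- as.vector(rowsum(vb, key))
    mean_d <- s1 / n
    var_d <- pmax(0, (s2 - n * mean_d^2) / pmax(1, n - 1))
    sd_d <- sqrt(var_d)
    tt <- ifelse(sd_d > 0, mean_d / (sd_d / sqrt(n)),
      ifelse(mean_d == 0, 0, Inf * sign(mean_d)))
    df <- n - 1
    p <- ifelse(n < 2, NA_real_,
      ifelse(sd_d > 0, 2 * pt(-abs(tt), df),
        ifelse(mean_d == 0, 1, 0)))
    degenerate <- sd_d == 0 & mean_d != 0
    ci <- as.integer(sub("_.*", "", ord_keys))
    cj <- as.integer(sub(".*_", "", ord_keys))
    out[[nm]] <- tibble::tibble(
      chrom1 = ba$chrom1,
      cell1_start = ba$offset1 + ci * grid_a$coarse,
      cell1_end = ba$offset1 + (ci + 1) * grid_a$coarse,
      chrom2 = ba$chrom2,
      cell2_start = ba$offset2 + cj * grid_a$coarse,
      cell2_end = ba$offset2 + (cj + 1) * grid_a$coarse,
      n = as.integer(n),
      mean_a = sa / n, mean_b = sb / n,
      mean_delta = mean_d, t = tt, df = df, p = p,
      degenerate = degenerate
    )
  }
  res <- dplyr::bind_rows(out)
  n_tests <- sum(!is.na(res$p))
  res$p_adj <- if (bonferroni) pmin(1, res$p * n_tests) else res$p
  res$favored <- dplyr::case_when(
    res$mean_delta > 0 ~ conds[2],
    res$mean_delta < 0 ~ conds[1],
    TRUE ~ NA_character_
  )
  attr(res, "conditions") <- conds
  attr(res, "bonferroni") <- bonferroni
  class(res) <- c("paired_grid_tests", class(res))
  res
}

#' Differential loops from a tested grid
#'
#' Splits the tested cells into two lists of rendered differential loops —
#' one per condition, keeping only cells whose delta favors that condition
#' (positive delta change). Per loop midpoint, only the cell with the
#' largest |delta| carries the test statistic (`stat_shown`). When an
#' aligned-border context is supplied, loops reaching past the midpoint of
#' the TAD adjacent to the aligned border are removed so left- and
#' right-border features do not mix.
#'
#' @param tests A `paired_grid_tests` tibble.
#' @param alpha Keep cells with `p_adj < alpha` (default 1 = keep all).
#' @param tads Optional [tad_set()] supplying midpoint-truncation context.
#' @param truncate Apply the TAD-midpoint truncation rule (requires `tads`).
#' @return A named list of two tibbles (one per condition), each with a
#'   `midpoint` column and logical `stat_shown`.
#' @export
differential_loops <- function(tests, alpha = 1, tads = NULL, truncate = FALSE) {
  conds <- attr(tests, "conditions") %||% c("A", "B")
  if (truncate) {
    assert_that(!is.null(tads),
      "midpoint truncation requested but no TAD alignment context supplied")
    tests <- truncate_past_tad_midpoint(tests, tads)
  }
  tests$midpoint <- (
    (tests$cell1_start + tests$cell1_end) / 2 +
      (tests$cell2_start + tests$cell2_end) / 2) / 2
  keep <- !is.na(tests$p_adj) & tests$p_adj < alpha
  out <- list()
  for (cond in conds) {
    sub <- tests[keep & !is.na(tests$favored) & tests$favored == cond, , drop = FALSE]
    if (nrow(sub) > 0) {
      sub <- dplyr::arrange(sub, .data$chrom1, .data$midpoint, -abs(.data$mean_delta))
      sub <- dplyr::group_by(sub, .data$chrom1, .data$midpoint)
      sub <- dplyr::mutate(sub, stat_shown = dplyr::row_number() == 1)
      sub <- dplyr::ungroup(sub)
    } else {
      sub$stat_shown <- logical(0)
      sub <- tibble::as_tibble(sub)
    }
    out[[cond]] <- sub
  }
  out
}

#' Remove grid cells whose ends reach past the midpoint of their TAD
#'
#' A cell end falling inside a TAD but beyond that TAD's midpoint (i.e.
#' closer to the opposite border than to the near one) disqualifies the
#' cell. Used when rendering border-aligned differential loops.
#'
#' @param tests A `paired_grid_tests` tibble.
#' @param tads A [tad_set()].
#' @return The filtered tibble (attributes preserved).
#' @export
truncate_past_tad_midpoint <- function(tests, tads) {
  e1 <- (tests$cell1_start + tests$cell1_end) / 2
  e2 <- (tests$cell2_start + tests$cell2_end) / 2
  # a loop spanning e1..e2 is dropped when it reaches across the midpoint of
  # a TAD containing one of its ends
  id1 <- tad_id_at(tests$chrom1, round(e1), tads)
  id2 <- tad_id_at(tests$chrom2, round(e2), tads)
  mid_of <- function(id) (tads$start[pmax(1, id)] + tads$end[pmax(1, id)]) / 2
  cross1 <- id1 > 0 & ((e1 < mid_of(id1) & e2 > mid_of(id1)) |
    (e2 < mid_of(id1) & e1 > mid_of(id1)))
  cross2 <- id2 > 0 & ((e1 < mid_of(id2) & e2 > mid_of(id2)) |
    (e2 < mid_of(id2) & e1 > mid_of(id2)))
  keep <- !(cross1 | cross2)
  out <- tests[keep, , drop = FALSE]
  attr(out, "conditions") <- attr(tests, "conditions")
  attr(out, "bonferroni") <- attr(tests, "bonferroni")
  class(out) <- class(tests)
  out
}
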