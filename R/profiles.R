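#' Z-score enrichment statistics over a positional profile
#'
#' Flags offset bins whose value falls outside the normal distribution of
#' the whole profile: each bin is standardized against the mean and sample
#' (n-1) standard deviation of all bins, and the two-tailed probability
#' from the central area of the standard normal gives its p-value. Tiers
#' mark p < 0.05, < 0.01 and < 0.005. A constant profile (zero sd) returns
#' all z = 0, p = 1.
#'
#' @param x Numeric vector of per-bin values, or a tibble with `offset` and
#'   `mean` columns (e.g. from [summarize_profile()]).
#' @return An `enrichment_profile` tibble: `offset`, `value`, `z`, `p`,
#'   `tier`.
#' @examples
#' zscore_profile(c(0, 0, 0, 10)) # z = 1.5 for the spike, p ~ 0.1336
#' @export
zscore_profile <- function(x) {
  if (is.data.frame(x)) {
    offset <- x$offset
    v <- x$mean
  } else {
    offset <- seq_along(x)
    v <- as.numeric(x)
  }
  assert_that(length(v) >= 3, "need at least 3 bins for a z profile")
  s <- sd(v)
  z <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  p <- 2 * pnorm(-abs(z))
  tier <- cut(p,
    breaks = c(-Inf, 0.005, 0.01, 0.05, Inf),
    labels = c("p<0.005", "p<0.01", "p<0.05", "ns")
  )
  structure(
    tibble::tibble(offset = offset, value = v, z = z, p = p, tier = tier),
    class = c("enrichment_profile", class(tibble::tibble()))
  )
}

#' Per-bin two-condition comparison via two-way ANOVA with Tukey contrast
#'
#' Compares two column-mean profiles block by block: within each block of
#' `k` consecutive bins, the k values of condition 1 and the k values of
#' condition 2 enter a two-way ANOVA (condition x bin position) and the
#' Tukey honest-significant-difference p-value of the condition contrast is
#' reported.
#'
#' @param colmeans_a,colmeans_b Tibbles with `offset` and `mean` over the
#'   same offsets (e.g. from [pileup_colmeans()]).
#' @param k Bins per block (default 5).
#' @return Tibble with `offset` (block left edge), per-condition block
#'   means, `diff` and Tukey `p`.
#' @export
compare_conditions_anova <- function(colmeans_a, colmeans_b, k = 5) {
  assert_that(nrow(colmeans_a) == nrow(colmeans_b),
    "profiles must share their offsets")
  blk <- (seq_len(nrow(colmeans_a)) - 1L) %/% k
  res <- lapply(unique(blk), function(b) {
    i <- which(blk == b)
    va <- colmeans_a$mean[i]
    vb <- colmeans_b$mean[i]
    d <- data.frame(
      value = c(va, vb),
      condition = factor(rep(c("a", "b"), each = length(i))),
      position = factor(rep(seq_along(i), 2))
    )
    p <- if (sd(d$value) == 0) {
      1
    } else {
      fit <- aov(value ~ condition + position, data = d)
      tk <- tryCatch(TukeyHSD(fit, "condition")$condition[, "p adj"],
        error = function(e) NA_real_)
      unname(tk)
    }
    tibble::tibble(
      offset = min(colmeans_a$offset[i]),
      mean_a = mean(va), mean_b = mean(vb),
      diff = mean(vb) - mean(va), p = p
    )
  })
  dplyr::bind_rows(res)
}

#' Zero-centered positional GO-category profiles around aligned loci
#'
#' For each GO category and each offset bin (pooled over all center loci),
#' computes the ratio of category gene count to total gene count in the
#' bin (genes assigned by TSS; bins without genes contribute 0), then
#' subtracts the category's average ratio over the whole span, so positive
#' values mark local clustering of the category. Pooled statistics average
#' all categories in `summary_k`-bin spans and pass them to
#' [zscore_profile()].
#'
#' @param expression Gene table with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param go_map Tibble with `gene_id` and `go_category`.
#' @param centers Tibble with `chrom`, `pos` of the aligned loci.
#' @param flank Half-span in bp (default 1 Mb).
#' @param bin Offset bin width in bp (default 1 kb).
#' @param summary_k Bins per pooled-summary span (default 5).
#' @param denominator `"bin"` (per-bin gene count, default) or `"span"`
#'   (total genes in the whole span).
#' @return List with `profiles` (long tibble: category, offset, ratio,
#'   centered) and `pooled` (an `enrichment_profile`).
#' @export
go_positional_profile <- function(expression, go_map, centers, flank = 1e6,
                                  bin = 1000, summary_k = 5,
                                  denominator = c("bin", "span")) {
  denominator <- match.arg(denominator)
  assert_that(nrow(go_map) > 0, "empty GO map")
  genes <- dplyr::inner_join(expression, go_map, by = "gene_id")
  assert_that(nrow(genes) > 0, "GO map covers no gene in the expression table")
  K <- as.integer(flank / bin)
  n_bins <- 2L * K
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  cats <- sort(unique(genes$go_category))
  cat_counts <- matrix(0L, length(cats), n_bins, dimnames = list(cats, NULL))
  tot_counts <- rep(0L, n_bins)
  for (r in seq_len(nrow(centers))) {
    ch <- centers$chrom[r]
    d <- tss - (centers$pos[r] - flank)
    in_span <- genes$chrom == ch & d >= 0 & d < 2 * flank
    if (!any(in_span)) next
    bidx <- floor(d[in_span] / bin) + 1L
    tot_counts <- tot_counts + tabulate(bidx, nbins = n_bins)
    for (ct in unique(genes$go_category[in_span])) {
      sel <- bidx[genes$go_category[in_span] == ct]
      cat_counts[ct, ] <- cat_counts[ct, ] + tabulate(sel, nbins = n_bins)
    }
  }
  denom <- if (denominator == "bin") {
    pmax(tot_counts, 1L) * (tot_counts > 0) + (tot_counts == 0)
  } else {
    rep(sum(tot_counts), n_bins)
  }
  offs <- seq(-K, K - 1L) * bin
  profiles <- purrr::map_dfr(cats, function(ct) {
    ratio <- as.numeric(cat_counts[ct, ]) / denom
    ratio[tot_counts == 0 & denominator == "bin"] <- 0
    tibble::tibble(
      category = ct, offset = offs, ratio = ratio,
      centered = ratio - mean(ratio)
    )
  })
  wide <- tidyr::pivot_wider(profiles[, c("category", "offset", "centered")],
    names_from = "category", values_from = "centered")
  pooled_bins <- rowMeans(as.matrix(wide[, -1, drop = FALSE]))
  blk <- (seq_len(n_bins) - 1L) %/% summary_k
  pooled <- tibble::tibble(
    offset = as.numeric(tapply(offs, blk, min)),
    mean = as.numeric(tapply(pooled_bins, blk, mean))
  )
  list(profiles = profiles, pooled = zscore_profile(pooled))
}
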