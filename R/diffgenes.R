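#' Rank interacting co-regulated gene pairs (DiffGene interactions)
#'
#' Filters loops to high confidence (q below `q_max`), scores each loop by
#' the sum over both anchors of the log2 fold changes of the
#' direction-consistent regulated genes contained in the anchor intervals
#' (direction `"up"` sums positive log2FC as-is; `"down"` sums the negated
#' log2FC of downregulated genes, i.e. the fold change read in the opposite
#' ratio), ranks loops from highest to lowest score, and greedily selects
#' down the list skipping any loop whose anchor midpoint lies within
#' `min_spacing` of an already selected midpoint on the same chromosome.
#'
#' @param loops A [loop_set()].
#' @param expression Gene table with `chrom`, `start`, `end`, `log2fc`, `q`.
#' @param direction `"up"` or `"down"`.
#' @param q_max Loop FDR cutoff (default 0.001).
#' @param top_n Number of interactions to return (default 200; fewer if
#'   fewer qualify).
#' @param min_spacing Minimum midpoint spacing in bp (default 2.5 Mb).
#' @param gene_mode `"body"` counts a gene when its body overlaps the
#'   anchor (default); `"tss"` requires the TSS inside the anchor.
#' @return A `diffgene_set` tibble: loop coordinates, `sum_log2fc`,
#'   `midpoint`, per-anchor gene counts and `rank`.
#' @export
rank_diffgenes <- function(loops, expression, direction = c("up", "down"),
                           q_max = 0.001, top_n = 200, min_spacing = 2.5e6,
                           gene_mode = c("body", "tss")) {
  direction <- match.arg(direction)
  gene_mode <- match.arg(gene_mode)
  loops <- filter_loops_q(loops, q_max)
  assert_that(nrow(loops) > 0, "no loops pass the q filter")
  sgn <- if (direction == "up") 1 else -1
  genes <- expression[sign(expression$log2fc) == sgn, , drop = FALSE]
  # direction-specific fold change: read so that regulated genes score > 0
  genes$value <- sgn * genes$log2fc
  gene_iv <- if (gene_mode == "tss") {
    tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
    tibble::tibble(chrom = genes$chrom, start = tss, end = tss + 1, value = genes$value)
  } else {
    tibble::tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
      value = genes$value)
  }
  anchor_sum <- function(chrom, start, end) {
    out_sum <- numeric(length(start))
    out_n <- integer(length(start))
    if (nrow(gene_iv) > 0) {
      h <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end)),
        intervals_to_granges(gene_iv)
      )
      qh <- S4Vectors::queryHits(h)
      if (length(qh) > 0) {
        agg <- rowsum(gene_iv$value[S4Vectors::subjectHits(h)], qh)
        out_sum[as.integer(rownames(agg))] <- agg[, 1]
        cnt <- rowsum(rep(1L, length(qh)), qh)
        out_n[as.integer(rownames(cnt))] <- cnt[, 1]
      }
    }
    list(sum = out_sum, n = out_n)
  }
  a1 <- anchor_sum(loops$chrom1, loops$start1, loops$end1)
  a2 <- anchor_sum(loops$chrom2, loops$start2, loops$end2)
  cand <- tibble::as_tibble(loops)
  cand$sum_log2fc <- a1$sum + a2$sum
  cand$n_genes1 <- a1$n
  cand$n_genes2 <- a2$n
  cand$midpoint <- loop_midpoints(loops)
  cand <- cand[cand$sum_log2fc > 0, , drop = FALSE]
  cand <- dplyr::arrange(cand, -.data$sum_log2fc,
    .data$chrom1, .data$start1, .data$start2)
  picked <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(picked) >= top_n) break
    ok <- TRUE
    if (length(picked) > 0) {
      same <- cand$chrom1[picked] == cand$chrom1[i]
      if (any(same) &&
        min(abs(cand$midpoint[picked][same] - cand$midpoint[i])) < min_spacing) {
        ok <- FALSE
      }
    }
    if (ok) picked <- c(picked, i)
  }
  out <- cand[picked, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  structure(out,
    direction = direction,
    class = c("diffgene_set", class(tibble::tibble()))
  )
}
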