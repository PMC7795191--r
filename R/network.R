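#' Build the top-N interaction network for one condition
#'
#' Ranks the coarse cells favored by a condition (positive delta toward it)
#' by their mean fine-pair strength in that condition, applies the optional
#' retention filters, keeps the top `n` cells and treats each as an
#' undirected edge between its two coarse bins. Per-node degree and local
#' clustering coefficient (triangles over possible triangles) are computed
#' from the adjacency matrix directly.
#'
#' @param tests A `paired_grid_tests` tibble.
#' @param n Number of top-ranked cells to keep (default 5000; clamped with a
#'   warning when fewer are available).
#' @param condition Which condition's favored network to build; defaults to
#'   the second condition of the comparison.
#' @param max_mean_strength Optional display-scale filter: drop cells whose
#'   favored-condition mean strength exceeds this value (the "omit average
#'   strength > 1" rule); `NULL` disables it.
#' @param percentile Optional retention filter keeping only cells at or
#'   above this percentile of favored-condition strength (e.g. 0.95);
#'   `NULL` disables it.
#' @return An `interaction_network`: list with `nodes` (node, degree,
#'   clustering) and `edges` (from, to, weight) tibbles.
#' @export
top_n_network <- function(tests, n = 5000, condition = NULL,
                          max_mean_strength = NULL, percentile = NULL) {
  conds <- attr(tests, "conditions") %||% c("A", "B")
  condition <- condition %||% conds[2]
  strength_col <- if (condition == conds[1]) "mean_a" else "mean_b"
  sub <- tests[!is.na(tests$favored) & tests$favored == condition, , drop = FALSE]
  strength <- sub[[strength_col]]
  if (!is.null(max_mean_strength)) {
    keep <- strength <= max_mean_strength
    sub <- sub[keep, , drop = FALSE]
    strength <- strength[keep]
  }
  if (!is.null(percentile)) {
    thr <- quantile(strength, percentile, names = FALSE)
    keep <- strength >= thr
    sub <- sub[keep, , drop = FALSE]
    strength <- strength[keep]
  }
  if (n > nrow(sub)) {
    warning(sprintf("only %d cells available; n clamped", nrow(sub)))
    n <- nrow(sub)
  }
  ord <- order(-strength, sub$chrom1, sub$cell1_start, sub$chrom2, sub$cell2_start)
  sub <- sub[ord[seq_len(n)], , drop = FALSE]
  edges <- tibble::tibble(
    from = paste0(sub$chrom1, ":", fmt_num(sub$cell1_start)),
    to = paste0(sub$chrom2, ":", fmt_num(sub$cell2_start)),
    weight = sub[[strength_col]]
  )
  network_from_edges(edges, condition = condition)
}

#' Network metrics from an edge list
#'
#' @param edges Tibble with `from`, `to` and optional `weight` columns;
#'   self-loops are dropped and duplicate edges collapsed.
#' @param condition Optional condition label stored on the result.
#' @return An `interaction_network` with per-node degree and clustering.
#' @export
network_from_edges <- function(edges, condition = NA_character_) {
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (!"weight" %in% names(edges)) edges$weight <- 1
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  nodes <- sort(unique(c(edges$from, edges$to)))
  k <- length(nodes)
  A <- matrix(0L, k, k, dimnames = list(nodes, nodes))
  A[cbind(match(edges$from, nodes), match(edges$to, nodes))] <- 1L
  A[cbind(match(edges$to, nodes), match(edges$from, nodes))] <- 1L
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  cc <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  structure(
    list(
      nodes = tibble::tibble(node = nodes, degree = unname(deg),
        clustering = unname(cc)),
      edges = tibble::as_tibble(edges),
      condition = condition
    ),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network> %d nodes, %d edges; mean degree %.2f, mean clustering %.3f\n",
    nrow(x$nodes), nrow(x$edges), mean(x$nodes$degree), mean(x$nodes$clustering)
  ))
  invisible(x)
}
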