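# broom-style tidiers for the fitted/result objects.

#' Tidy a border-shift comparison
#'
#' @param x A `border_shift` from [compare_tads()].
#' @param ... Unused.
#' @return Per-border tibble of nearest-neighbor distances.
#' @export
tidy.border_shift <- function(x, ...) x$per_border

#' @rdname tidy.border_shift
#' @export
glance.border_shift <- function(x, ...) x$stats

#' Tidy an interaction network
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return Per-node tibble with degree and clustering coefficient.
#' @export
tidy.interaction_network <- function(x, ...) x$nodes

#' @rdname tidy.interaction_network
#' @export
glance.interaction_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    mean_degree = mean(x$nodes$degree),
    mean_clustering = mean(x$nodes$clustering),
    condition = x$condition
  )
}

#' Tidy a pile-up matrix into long form
#'
#' @param x A [pileup_matrix()].
#' @param ... Unused.
#' @return Long tibble: `locus`, `offset`, `value`, `masked`.
#' @export
tidy.pileup_matrix <- function(x, ...) {
  tibble::tibble(
    locus = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    offset = rep(x$offsets, each = nrow(x$values)),
    value = as.vector(x$values),
    masked = as.vector(x$mask)
  )
}

#' Tidy a same-size TAD stack
#'
#' @param x A `tad_stack` from [stack_same_size()].
#' @param ... Unused.
#' @return The per-attribute correlation tibble.
#' @export
tidy.tad_stack <- function(x, ...) x$correlations

#' @rdname tidy.tad_stack
#' @export
glance.tad_stack <- function(x, ...) {
  tibble::tibble(
    n_tads = nrow(x$pileups[[1]]$rows),
    sort_attr = x$sort_attr,
    n_attrs = length(x$pileups) - 1
  )
}

#' Tidy a class-prediction fit
#'
#' @param x A `class_fit` from [train_eval()].
#' @param ... Unused.
#' @return The test confusion matrix in long form.
#' @export
tidy.class_fit <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$confusion))
}

#' @rdname tidy.class_fit
#' @export
glance.class_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    train_accuracy = x$train_accuracy,
    test_accuracy = x$test_accuracy,
    n_train = x$n_train,
    n_test = x$n_test
  )
}

#' Tidy a qPCR analysis
#'
#' @param x A `qpcr_result` from [aggregate_and_compare()].
#' @param ... Unused.
#' @return The per-cell quantification tibble.
#' @export
tidy.qpcr_result <- function(x, ...) {
  dplyr::left_join(x$cells, x$lsd_tests,
    by = c("assay", "target", "condition", "treatment"))
}

#' @rdname tidy.qpcr_result
#' @export
glance.qpcr_result <- function(x, ...) {
  tibble::tibble(
    n_targets = length(unique(x$cells$target)),
    n_cells = nrow(x$cells),
    n_significant = sum(x$lsd_tests$p < 0.05)
  )
}
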