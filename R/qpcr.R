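#' qPCR quantification formulas
#'
#' The three printed quantification formulas, applied verbatim:
#' * 3C-qPCR percent input of a non-digested reference locus:
#'   `[100 * 2^(reference CT - interaction CT)] * 100`
#' * ChIP-qPCR percent of 10% input: `100 * 2^(input CT - IP CT)`
#' * RT-qPCR relative expression: `[100 * 2^(-cDNA CT)] * 10^6`
#'
#' All are strictly decreasing in the sample CT: one extra cycle to
#' threshold halves the quantity.
#'
#' @param gapdh_ct,interaction_ct,input10_ct,ip_ct,cdna_ct Cycle-threshold
#'   values (finite reals).
#' @return Numeric quantity on the percent (or expression-unit) scale.
#' @examples
#' percent_input_3c(20, 25) # 312.5
#' percent_input_chip(20, 20) # 100
#' relative_expression(20) # ~95.37
#' @name qpcr-formulas
NULL

#' @rdname qpcr-formulas
#' @export
percent_input_3c <- function(gapdh_ct, interaction_ct) {
  assert_that(all(is.finite(gapdh_ct)) && all(is.finite(interaction_ct)),
    "CT values must be finite")
  (100 * 2^(gapdh_ct - interaction_ct)) * 100
}

#' @rdname qpcr-formulas
#' @export
percent_input_chip <- function(input10_ct, ip_ct) {
  assert_that(all(is.finite(input10_ct)) && all(is.finite(ip_ct)),
    "CT values must be finite")
  100 * 2^(input10_ct - ip_ct)
}

#' @rdname qpcr-formulas
#' @export
relative_expression <- function(cdna_ct) {
  assert_that(all(is.finite(cdna_ct)), "CT values must be finite")
  (100 * 2^(-1 * cdna_ct)) * 1e6
}

quantify_sample <- function(assay, ct, reference_ct) {
  switch(assay,
    "3C" = percent_input_3c(reference_ct, ct),
    ChIP = percent_input_chip(reference_ct, ct),
    RT = relative_expression(ct),
    abort_bad(paste("unknown assay:", assay))
  )
}

#' Aggregate qPCR replicates and compare treatments
#'
#' Quantifies each well with the assay's formula, averages technical
#' replicates within each biological replicate first, then summarizes the
#' biological replicates per target and condition x treatment cell (mean
#' and SEM). Fold changes are ratios of treated to control biological-
#' replicate means, with the SEM propagated by the delta method. Per
#' target, significance of the treatment contrast within each condition
#' uses Fisher's LSD after a two-way ANOVA (condition x treatment) on the
#' biological-replicate values: a t-test on the cell means using the
#' pooled ANOVA residual mean square. In a single-factor two-group design
#' this reduces to the pooled-variance t-test.
#'
#' @param samples Long-format tibble: `assay` (`"3C"`, `"ChIP"`, `"RT"`),
#'   `condition`, `treatment`, `target`, `bio_rep`, `tech_rep`, `ct` and
#'   `reference_ct` (NA allowed for RT).
#' @param control Treatment level serving as the fold-change denominator
#'   (default `"control"`).
#' @return A `qpcr_result` list with `cells` (per-cell means +/- SEM),
#'   `fold_changes` and `lsd_tests` tibbles.
#' @export
aggregate_and_compare <- function(samples, control = "control") {
  samples <- tibble::as_tibble(samples)
  need <- c("assay", "condition", "treatment", "target", "bio_rep", "tech_rep", "ct")
  assert_that(all(need %in% names(samples)),
    paste("`samples` needs columns:", paste(need, collapse = ", ")))
  if (!"reference_ct" %in% names(samples)) samples$reference_ct <- NA_real_
  samples$quantity <- vapply(seq_len(nrow(samples)), function(i) {
    quantify_sample(samples$assay[i], samples$ct[i], samples$reference_ct[i])
  }, numeric(1))
  # technical replicates first, then biological
  bio <- dplyr::summarise(
    dplyr::group_by(samples, .data$assay, .data$target, .data$condition,
      .data$treatment, .data$bio_rep),
    quantity = mean(.data$quantity), .groups = "drop"
  )
  cells <- dplyr::summarise(
    dplyr::group_by(bio, .data$assay, .data$target, .data$condition,
      .data$treatment),
    n = dplyr::n(),
    mean = mean(.data$quantity),
    sem = sd(.data$quantity) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  assert_that(all(cells$n >= 2),
    "every condition x treatment cell needs >= 2 biological replicates")
  # fold changes: each non-control treatment vs control within condition
  fc <- list()
  for (key in unique(paste(cells$assay, cells$target, cells$condition, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- cells[cells$assay == parts[1] & cells$target == parts[2] &
      cells$condition == parts[3], , drop = FALSE]
    ctrl <- sub[sub$treatment == control, , drop = FALSE]
    if (nrow(ctrl) != 1) next
    for (tr in setdiff(sub$treatment, control)) {
      trt <- sub[sub$treatment == tr, , drop = FALSE]
      fold <- trt$mean / ctrl$mean
      # delta-method SEM of the ratio
      fold_sem <- abs(fold) * sqrt((trt$sem / trt$mean)^2 + (ctrl$sem / ctrl$mean)^2)
      fc[[length(fc) + 1]] <- tibble::tibble(
        assay = parts[1], target = parts[2], condition = parts[3],
        treatment = tr, fold_change = fold, fold_sem = fold_sem
      )
    }
  }
  # Fisher's LSD on the treatment contrast per target, pooled over the
  # two-way (condition x treatment) ANOVA residual
  lsd <- list()
  for (key in unique(paste(bio$assay, bio$target, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- bio[bio$assay == parts[1] & bio$target == parts[2], , drop = FALSE]
    two_way <- length(unique(sub$condition)) > 1
    fml <- if (two_way) {
      quantity ~ factor(condition) * factor(treatment)
    } else {
      quantity ~ factor(treatment)
    }
    fit <- aov(fml, data = sub)
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    for (cond in unique(sub$condition)) {
      sc <- sub[sub$condition == cond, , drop = FALSE]
      ctrl_v <- sc$quantity[sc$treatment == control]
      for (tr in setdiff(unique(sc$treatment), control)) {
        trt_v <- sc$quantity[sc$treatment == tr]
        if (length(ctrl_v) < 2 || length(trt_v) < 2) next
        tstat <- (mean(trt_v) - mean(ctrl_v)) /
          sqrt(mse * (1 / length(trt_v) + 1 / length(ctrl_v)))
        pval <- 2 * pt(-abs(tstat), fit$df.residual)
        lsd[[length(lsd) + 1]] <- tibble::tibble(
          assay = parts[1], target = parts[2], condition = cond,
          treatment = tr, t = tstat, df = fit$df.residual, p = pval
        )
      }
    }
  }
  structure(
    list(
      cells = cells,
      fold_changes = dplyr::bind_rows(fc),
      lsd_tests = dplyr::bind_rows(lsd)
    ),
    class = "qpcr_result"
  )
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat(sprintf(
    "<qpcr_result> %d cells, %d fold changes, %d LSD tests\n",
    nrow(x$cells), nrow(x$fold_changes), nrow(x$lsd_tests)
  ))
  invisible(x)
}
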