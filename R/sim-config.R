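#' Configuration for the synthetic two-condition genome generator
#'
#' Bundles every knob of the simulator with validated defaults. The defaults
#' describe the study conditions the pipeline is exercised under: a small
#' multi-chromosome genome with distance-decaying contact background,
#' planted TADs in the common size range, a minority of borders reorganized
#' between the two cell states, condition-specific differential loops,
#' border-enriched protein binding, and TAD-coupled co-regulated expression.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp; must be divisible by
#'   1000 (and by the contact-matrix bin to simulate matrices).
#' @param tad_size_range Min/max planted TAD size in bp (min >= 120 kb).
#' @param decay_exponent Power-law exponent alpha of the contact-distance
#'   decay, P(contact) proportional to d^-alpha.
#' @param intra_tad_enrichment Fold enrichment of contacts whose two ends
#'   fall in the same TAD (>= 1).
#' @param border_loop_enrichment Fold enrichment of loops with both anchors
#'   within one 40 kb bin of a TAD border (>= 1).
#' @param n_diff_loops Number of planted condition-specific loops.
#' @param diff_loop_fold Fold by which a planted loop is stronger in its
#'   favored condition (>= 1).
#' @param n_genes Number of simulated genes.
#' @param tad_coregulation_prob Probability that a gene adopts the shared
#'   regulation sign of the TAD containing its TSS.
#' @param border_peak_enrichment Fold enrichment of binding-peak density
#'   within +/-20 kb of TAD borders over the genome-wide density (>= 1).
#' @param fpkm_lognormal_params `c(mu, sigma)` of the baseline FPKM
#'   log-normal.
#' @param read_depth Total loop-score mass per condition (expected sum of
#'   Poisson loop scores).
#' @param n_loops Number of loop records per condition.
#' @param n_peaks_per_protein Binding peaks per protein per condition.
#' @param border_change_prob Fraction of interior TAD borders repositioned
#'   in the second condition.
#' @param conditions Two condition labels.
#' @param seed Master integer seed; every output derives its own RNG stream
#'   from it, so outputs are reproducible file-by-file.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2,
                       chrom_length = 20e6,
                       tad_size_range = c(240e3, 960e3),
                       decay_exponent = 1,
                       intra_tad_enrichment = 3,
                       border_loop_enrichment = 3,
                       n_diff_loops = 50,
                       diff_loop_fold = 4,
                       n_genes = 2000,
                       tad_coregulation_prob = 0.8,
                       border_peak_enrichment = 5,
                       fpkm_lognormal_params = c(1, 1.2),
                       read_depth = 1e6,
                       n_loops = 20000,
                       n_peaks_per_protein = 1000,
                       border_change_prob = 0.38,
                       conditions = c("ESC", "NCC"),
                       seed = 1L) {
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = chrom_length,
    tad_size_range = tad_size_range, decay_exponent = decay_exponent,
    intra_tad_enrichment = intra_tad_enrichment,
    border_loop_enrichment = border_loop_enrichment,
    n_diff_loops = as.integer(n_diff_loops), diff_loop_fold = diff_loop_fold,
    n_genes = as.integer(n_genes),
    tad_coregulation_prob = tad_coregulation_prob,
    border_peak_enrichment = border_peak_enrichment,
    fpkm_lognormal_params = fpkm_lognormal_params,
    read_depth = read_depth, n_loops = as.integer(n_loops),
    n_peaks_per_protein = as.integer(n_peaks_per_protein),
    border_change_prob = border_change_prob,
    conditions = conditions, seed = as.integer(seed)
  )
  assert_that(cfg$n_chroms >= 1, "need at least one chromosome")
  assert_that(cfg$chrom_length %% 1000 == 0,
    "`chrom_length` must be divisible by 1000")
  assert_that(length(cfg$tad_size_range) == 2 &&
    cfg$tad_size_range[1] >= 3 * 40000 &&
    cfg$tad_size_range[1] <= cfg$tad_size_range[2],
    "`tad_size_range` min must be >= 120 kb and <= max")
  folds <- c(cfg$intra_tad_enrichment, cfg$border_loop_enrichment,
    cfg$diff_loop_fold, cfg$border_peak_enrichment)
  assert_that(all(folds >= 1), "all fold enrichments must be >= 1")
  probs <- c(cfg$tad_coregulation_prob, cfg$border_change_prob)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  assert_that(length(cfg$conditions) == 2 && !anyDuplicated(cfg$conditions),
    "`conditions` must be two distinct labels")
  assert_that(cfg$read_depth > 0 && cfg$n_loops > 0, "depth and loop count must be positive")
  structure(cfg, class = "sim_config")
}

sim_chroms <- function(config) {
  paste0("chr", seq_len(config$n_chroms))
}

sim_chrom_sizes <- function(config) {
  tibble::tibble(
    chrom = sim_chroms(config),
    size = rep(config$chrom_length, config$n_chroms)
  )
}
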