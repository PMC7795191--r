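# Border resampling enrichment: motif (PWM) or k-mer counting in random
# fixed-width samples drawn within offset bins around aligned TAD borders.

#' Simulate random DNA sequence with optional planted motif instances
#'
#' Generates uniform-random DNA per chromosome and overwrites substrings
#' with planted motif instances at the requested per-kb rate inside the
#' given intervals. A stand-in for real genome sequence in enrichment
#' analyses; labelled synthetic throughout.
#'
#' @param chrom_sizes Chromosome sizes (data frame or named vector).
#' @param seed Integer seed.
#' @param plant Optional tibble with `chrom`, `start`, `end`, `motif`
#'   (DNA string), `rate_per_kb` (expected instances per kb).
#' @return Named character vector of chromosome sequences.
#' @export
simulate_sequence <- function(chrom_sizes, seed = 1L, plant = NULL) {
  cs <- as_chrom_sizes(chrom_sizes)
  seqs <- setNames(vector("character", nrow(cs)), cs$chrom)
  for (i in seq_len(nrow(cs))) {
    seqs[[cs$chrom[i]]] <- with_stream(seed, paste0("seq_", cs$chrom[i]), {
      paste(sample(c("A", "C", "G", "T"), cs$size[i], replace = TRUE),
        collapse = "")
    })
  }
  if (!is.null(plant)) {
    seqs <- with_stream(seed, "seq_plant", {
      for (r in seq_len(nrow(plant))) {
        m <- plant$motif[r]
        L <- nchar(m)
        width <- plant$end[r] - plant$start[r]
        n_inst <- rpois(1, plant$rate_per_kb[r] * width / 1000)
        if (n_inst == 0) next
        pos <- floor(runif(n_inst, plant$start[r], plant$end[r] - L))
        s <- seqs[[plant$chrom[r]]]
        for (p in pos) substr(s, p + 1, p + L) <- m
        seqs[[plant$chrom[r]]] <- s
      }
      seqs
    })
  }
  seqs
}

count_motif_hits <- function(fragments, motif, mode, min_score = "80%") {
  if (mode == "kmer") {
    return(sum(stringr::str_count(fragments, stringr::fixed(motif))))
  }
  assert_that(requireNamespace("Biostrings", quietly = TRUE),
    "PWM scanning requires the Biostrings package")
  sum(vapply(fragments, function(fr) {
    Biostrings::countPWM(motif, Biostrings::DNAString(fr), min.score = min_score)
  }, numeric(1)))
}

#' Binned resampling enrichment of motifs around aligned borders
#'
#' Repeatedly samples fixed-width subsequences at random positions within
#' each offset bin around the aligned borders (pooled over borders), counts
#' motif occurrences — position-weight-matrix hits above a log-odds
#' threshold in `"pwm"` mode, exact matches of supplied k-mers in `"kmer"`
#' mode — and averages the per-bin counts over iterations. Motifs counted
#' `min_count` times or fewer in total are dropped as likely false
#' positives. Per motif, a z-score across bins with its two-tailed p is
#' computed and Bonferroni-adjusted for the number of motifs tested. Bins
#' lying past a border's own TAD midpoint are excluded from sampling when
#' `max_inward` is supplied.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param borders Tibble with `chrom`, `pos`, `side` (`"left"`/`"right"`)
#'   and optionally `max_inward` (bp usable inward before the TAD
#'   midpoint).
#' @param motifs For `"pwm"` mode a named list of 4 x L probability
#'   matrices (rows A, C, G, T); for `"kmer"` mode a character vector of
#'   k-mers (named or not).
#' @param mode `"pwm"` or `"kmer"`.
#' @param bin Offset bin width in bp (default 10 kb).
#' @param span One-sided span in bp (default 195 kb).
#' @param n_iter Iterations averaged together (default 50).
#' @param n_repeat Sampling repeats per iteration (default 10).
#' @param n_samples Samples per repeat per bin (default 1000).
#' @param sample_width Sampled subsequence width (default 100 bp; the
#'   k-mer protocol uses 20 bp).
#' @param min_count Drop motifs with total count <= this (default 10).
#' @param min_score PWM log-odds threshold (default `"80%"` of the maximum).
#' @param seed Integer seed (sampling is deterministic given the seed).
#' @return A tibble: `motif`, `offset`, `mean_count`, `z`, `p`, `p_adj`.
#' @export
border_resampling_enrichment <- function(seqs, borders, motifs,
                                         mode = c("pwm", "kmer"),
                                         bin = 10000, span = 195000,
                                         n_iter = 50, n_repeat = 10,
                                         n_samples = 1000,
                                         sample_width = if (mode == "kmer") 20 else 100,
                                         min_count = 10, min_score = "80%",
                                         seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "pwm") {
    assert_that(is.list(motifs) && length(motifs) > 0,
      "PWM mode requires a named list of position weight matrices")
  }
  motif_names <- names(motifs) %||% paste0("motif", seq_along(motifs))
  if (is.null(names(motifs))) names(motifs) <- motif_names
  K <- as.integer(span / bin)
  offs <- seq(-K, K - 1L) * bin
  n_bins <- length(offs)
  counts <- array(0,
    dim = c(length(motifs), n_bins, n_iter),
    dimnames = list(motif_names, NULL, NULL)
  )
  if (!"max_inward" %in% names(borders)) borders$max_inward <- Inf
  # genomic sampling window of each (border, offset bin), honoring midpoint
  # truncation: inward offsets beyond max_inward are unusable for a border
  windows <- list()
  for (b in seq_len(nrow(borders))) {
    inward_sign <- if (borders$side[b] == "left") 1 else -1
    for (j in seq_len(n_bins)) {
      inward_off <- inward_sign * (offs[j] + bin / 2)
      if (inward_off > borders$max_inward[b]) next
      lo <- borders$pos[b] + offs[j]
      hi <- lo + bin - sample_width
      if (lo < 0 || hi > nchar(seqs[[borders$chrom[b]]]) - sample_width) next
      windows[[length(windows) + 1]] <- list(
        bin = j, chrom = borders$chrom[b], lo = lo, hi = hi
      )
    }
  }
  bin_windows <- split(windows, vapply(windows, `[[`, integer(1), "bin"))
  with_stream(seed, "border_resampling", {
    for (it in seq_len(n_iter)) {
      for (jname in names(bin_windows)) {
        j <- as.integer(jname)
        wins <- bin_windows[[jname]]
        total <- setNames(rep(0, length(motifs)), motif_names)
        for (rep_ in seq_len(n_repeat)) {
          pick <- sample.int(length(wins), n_samples, replace = TRUE)
          starts <- vapply(pick, function(k) {
            floor(runif(1, wins[[k]]$lo, wins[[k]]$hi + 1))
          }, numeric(1))
          frags <- vapply(seq_along(pick), function(q) {
            substr(seqs[[wins[[pick[q]]]$chrom]], starts[q] + 1,
              starts[q] + sample_width)
          }, character(1))
          for (m in motif_names) {
            total[m] <- total[m] + count_motif_hits(frags, motifs[[m]], mode, min_score)
          }
        }
        counts[, j, it] <- total / n_repeat
      }
    }
  })
  mean_counts <- apply(counts, c(1, 2), mean)
  keep <- rowSums(apply(counts, c(1, 2), sum)) > min_count
  mean_counts <- mean_counts[keep, , drop = FALSE]
  n_motifs <- sum(keep)
  out <- purrr::map_dfr(rownames(mean_counts), function(m) {
    prof <- zscore_profile(mean_counts[m, ])
    tibble::tibble(
      motif = m, offset = offs, mean_count = mean_counts[m, ],
      z = prof$z, p = prof$p, p_adj = pmin(1, prof$p * n_motifs)
    )
  })
  out
}
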