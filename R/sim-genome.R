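# Synthetic two-condition genome generator.  Planted structure (TADs,
# differential loops, border peaks, co-regulated genes) is returned as a
# `SyntheticTruth` list so downstream recovery can be scored against it.

# --- planted TADs ---------------------------------------------------------

sim_tads_one_chrom <- function(chrom, length_bp, size_range) {
  starts <- integer(0)
  sizes <- integer(0)
  pos <- 0
  while (pos < length_bp) {
    sz <- round(runif(1, size_range[1], size_range[2]) / 40000) * 40000
    sz <- max(sz, 120000)
    if (pos + sz > length_bp) sz <- length_bp - pos
    if (sz < 120000) {
      # fold the remainder into the previous domain
      sizes[length(sizes)] <- sizes[length(sizes)] + sz
      break
    }
    starts <- c(starts, pos)
    sizes <- c(sizes, sz)
    pos <- pos + sz
  }
  tibble::tibble(chrom = chrom, start = starts, end = starts + sizes)
}

sim_tads_condition1 <- function(config) {
  cs <- sim_chrom_sizes(config)
  purrr::map2_dfr(cs$chrom, cs$size, sim_tads_one_chrom,
    size_range = config$tad_size_range)
}

# second condition: reposition a fraction of interior borders by >= 1 bin
sim_tads_condition2 <- function(config, tads1) {
  out <- dplyr::group_modify(dplyr::group_by(tads1, .data$chrom), function(d, key) {
    borders <- c(d$start[1], d$end) # interior borders are d$end[-last]
    n_int <- length(borders) - 2
    if (n_int > 0) {
      for (k in seq_len(n_int) + 1) {
        if (runif(1) < config$border_change_prob) {
          shift <- sample(c(-1, 1), 1) * sample(1:5, 1) * 40000
          cand <- borders[k] + shift
          if (cand - borders[k - 1] >= 120000 && borders[k + 1] - cand >= 120000) {
            borders[k] <- cand
          }
        }
      }
    }
    tibble::tibble(
      start = borders[-length(borders)],
      end = borders[-1]
    )
  })
  dplyr::ungroup(out)[, c("chrom", "start", "end")]
}

borders_of <- function(tads) {
  dplyr::distinct(dplyr::arrange(tibble::tibble(
    chrom = rep(tads$chrom, 2),
    pos = c(tads$start, tads$end)
  ), .data$chrom, .data$pos))
}

# --- helpers --------------------------------------------------------------

# inverse-CDF sample from a truncated power law p(d) ~ d^-alpha
sample_power_law <- function(n, alpha, dmin, dmax) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-12) {
    dmin * (dmax / dmin)^u
  } else {
    (dmin^(1 - alpha) + u * (dmax^(1 - alpha) - dmin^(1 - alpha)))^(1 / (1 - alpha))
  }
}

# TAD id containing each position (0 if none); tads assumed sorted per chrom
tad_id_at <- function(chrom, pos, tads) {
  gr_pos <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  gr_tad <- intervals_to_granges(tads)
  hit <- GenomicRanges::findOverlaps(gr_pos, gr_tad, select = "first")
  ifelse(is.na(hit), 0L, hit)
}

near_border <- function(chrom, pos, borders, slack = 40000) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    b <- borders$pos[borders$chrom == ch]
    idx <- which(chrom == ch)
    if (length(b) == 0) next
    out[idx] <- vapply(pos[idx], function(p) min(abs(b - p)) <= slack, logical(1))
  }
  out
}

# --- main entry point -----------------------------------------------------

#' Simulate a two-condition genome with planted chromatin structure
#'
#' Generates, for two cell-state conditions: TAD partitions (a configurable
#' fraction of borders repositioned in condition 2), loop sets whose
#' Poisson scores follow a distance power-law background modulated by
#' within-TAD and border enrichment plus planted condition-specific
#' differential loops, border-enriched binding peaks for two proteins,
#' genes with TAD-coupled co-regulated expression, GO labels with
#' positional (per-TAD) clustering, and BED annotation tracks. Each output
#' draws from its own RNG stream derived from the master seed, so runs with
#' the same seed are byte-identical file-by-file and adding an output never
#' perturbs the others.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, all outputs are written in
#'   the standard formats (chrom.sizes, BED, narrowPeak, BEDPE, TSV).
#' @param write_matrices Also simulate and write 40 kb contact matrices.
#' @return A list with `truth` (planted structure), `data` (in-memory
#'   tibbles and [loop_set()]s) and `files` (paths, when `out_dir` given).
#' @export
simulate_genome <- function(config, out_dir = NULL, write_matrices = FALSE) {
  assert_that(inherits(config, "sim_config"), "`config` must come from sim_config()")
  seed <- config$seed
  conds <- config$conditions

  tads1 <- with_stream(seed, "tads", sim_tads_condition1(config))
  tads2 <- with_stream(seed, "tads2", sim_tads_condition2(config, tads1))
  tads <- setNames(list(tads1, tads2), conds)
  borders <- lapply(tads, borders_of)

  peaks <- sim_peaks(config, borders)
  genes <- with_stream(seed, "genes", sim_genes(config))
  expr <- with_stream(seed, "expression", sim_expression(config, genes, tads[[2]]))
  go <- with_stream(seed, "go", sim_go_labels(config, expr, tads[[2]]))
  annot <- with_stream(seed, "annotations", sim_annotations(config, expr))
  loops <- sim_loops(config, tads, borders)

  # protein-associated loop subsets: loops with an anchor overlapping a peak
  subset_loops <- function(ls, pk) {
    gr1 <- GenomicRanges::GRanges(ls$chrom1, IRanges::IRanges(ls$start1 + 1L, ls$end1))
    gr2 <- GenomicRanges::GRanges(ls$chrom2, IRanges::IRanges(ls$start2 + 1L, ls$end2))
    grp <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end))
    keep <- IRanges::overlapsAny(gr1, grp) | IRanges::overlapsAny(gr2, grp)
    out <- ls[keep, , drop = FALSE]
    attr(out, "condition") <- attr(ls, "condition")
    attr(out, "total_valid_pairs") <- sum(out$score)
    class(out) <- class(ls)
    out
  }
  assay_loops <- list()
  for (cond in conds) {
    assay_loops[[paste0("hic_", cond)]] <- loops$sets[[cond]]
    for (prot in c("fgfr1", "ctcf")) {
      assay_loops[[paste0(prot, "_", cond)]] <-
        subset_loops(loops$sets[[cond]], peaks$peaks[[paste0(prot, "_", cond)]])
    }
  }

  truth <- list(
    tads = tads,
    tad_borders_per_condition = borders,
    diff_loops = loops$diff_loops,
    coregulated_gene_groups = expr$groups,
    border_peak_positions = peaks$border_positions
  )
  data <- list(
    chrom_sizes = sim_chrom_sizes(config),
    loops = assay_loops,
    peaks = peaks$peaks,
    expression = expr$table,
    go_labels = go,
    annotations = annot
  )

  files <- NULL
  if (!is.null(out_dir)) {
    files <- write_sim_outputs(config, data, out_dir)
    if (write_matrices) {
      mats <- simulate_contact_matrix(config, truth)
      dir.create(file.path(out_dir, "matrices"), showWarnings = FALSE, recursive = TRUE)
      for (cond in names(mats)) {
        for (ch in names(mats[[cond]])) {
          p <- file.path(out_dir, "matrices", paste0(cond, "_", ch, ".tsv"))
          write_contact_matrix(mats[[cond]][[ch]], p)
          files <- c(files, p)
        }
      }
    }
  }
  list(truth = truth, data = data, files = files)
}

# --- binding peaks --------------------------------------------------------

sim_peaks <- function(config, borders) {
  L <- config$chrom_length * config$n_chroms
  cs <- sim_chrom_sizes(config)
  peaks <- list()
  border_positions <- list()
  for (prot in c("fgfr1", "ctcf")) {
    for (ci in 1:2) {
      cond <- config$conditions[ci]
      label <- paste0(prot, "_", cond)
      res <- with_stream(config$seed, paste0("peaks_", label), {
        b <- borders[[cond]]
        n <- config$n_peaks_per_protein
        win <- 20000
        lb <- nrow(b) * 2 * win
        e <- config$border_peak_enrichment
        n_border <- min(n, round(n * (e - 1) * (lb / L) / (1 - lb / L)))
        # border-window peaks
        bi <- sample.int(nrow(b), n_border, replace = TRUE)
        bpos <- pmax(0, pmin(
          config$chrom_length - 400,
          b$pos[bi] + round(runif(n_border, -win, win))
        ))
        bchrom <- b$chrom[bi]
        # genome-wide background
        gchrom <- sample(cs$chrom, n - n_border, replace = TRUE)
        gpos <- floor(runif(n - n_border, 0, config$chrom_length - 400))
        start <- c(bpos, gpos)
        chrom <- c(bchrom, gchrom)
        sig <- round(rlnorm(n, 2, 0.6), 3)
        pk <- tibble::tibble(
          chrom = chrom, start = start, end = start + 400,
          name = paste0(label, "_peak", seq_len(n)),
          score = pmin(1000L, as.integer(round(sig * 100))),
          strand = ".",
          signalValue = sig,
          pValue = -1, qValue = -1, peak = 200L
        )
        list(
          pk = dplyr::arrange(pk, .data$chrom, .data$start),
          border_pos = tibble::tibble(
            protein = prot, condition = cond,
            chrom = bchrom, pos = bpos + 200
          )
        )
      })
      peaks[[label]] <- res$pk
      border_positions[[label]] <- res$border_pos
    }
  }
  list(peaks = peaks, border_positions = dplyr::bind_rows(border_positions))
}

# --- genes, expression, GO ------------------------------------------------

sim_genes <- function(config) {
  cs <- sim_chrom_sizes(config)
  n <- config$n_genes
  chrom <- sample(cs$chrom, n, replace = TRUE)
  len <- round(runif(n, 2000, 50000))
  start <- floor(runif(n, 10000, config$chrom_length - 60000))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tibble::tibble(
    gene_id = sprintf("gene%04d", seq_len(n)),
    chrom = chrom, start = start, end = start + len, strand = strand
  )
}

sim_expression <- function(config, genes, tads_grouping) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  tad_id <- paste0(
    genes$chrom, ":",
    tad_id_at(genes$chrom, tss, tads_grouping)
  )
  # per-TAD latent regulation sign
  tad_sign <- setNames(
    sample(c(-1, 1), length(unique(tad_id)), replace = TRUE),
    unique(tad_id)
  )
  adopt <- runif(nrow(genes)) < config$tad_coregulation_prob
  sign <- ifelse(adopt, tad_sign[tad_id], -tad_sign[tad_id])
  l2fc <- sign * (0.2 + stats::rexp(nrow(genes), rate = 1))
  q <- pmin(1, 2 * pnorm(-abs(l2fc) / 0.3))
  mu <- config$fpkm_lognormal_params[1]
  sg <- config$fpkm_lognormal_params[2]
  fpkm1 <- rlnorm(nrow(genes), mu, sg)
  fpkm2 <- fpkm1 * 2^l2fc
  tab <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = genes$start, end = genes$end, strand = genes$strand,
    fpkm_1 = round(fpkm1, 4), fpkm_2 = round(fpkm2, 4),
    log2fc = round(l2fc, 4), q = signif(q, 4)
  )
  names(tab)[names(tab) == "fpkm_1"] <- paste0("fpkm_", config$conditions[1])
  names(tab)[names(tab) == "fpkm_2"] <- paste0("fpkm_", config$conditions[2])
  groups <- split(genes$gene_id, tad_id)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  group_sign <- tad_sign[names(groups)]
  list(
    table = tab,
    groups = purrr::map2(groups, group_sign, function(g, s) list(genes = g, sign = s))
  )
}

sim_go_labels <- function(config, expr, tads_grouping) {
  categories <- c(
    "proliferation", "metabolic", "developmental", "transcription",
    "neuronal", "adhesion", "signaling", "cytoskeleton", "transport",
    "apoptosis"
  )
  tab <- expr$table
  tss <- ifelse(tab$strand == "+", tab$start, tab$end - 1)
  tad_id <- paste0(tab$chrom, ":", tad_id_at(tab$chrom, tss, tads_grouping))
  dominant <- setNames(
    sample(categories, length(unique(tad_id)), replace = TRUE),
    unique(tad_id)
  )
  use_dom <- runif(nrow(tab)) < 0.5
  cat <- ifelse(use_dom, dominant[tad_id],
    sample(categories, nrow(tab), replace = TRUE))
  tibble::tibble(gene_id = tab$gene_id, go_category = cat)
}

# --- annotation tracks ----------------------------------------------------

sim_annotations <- function(config, expr) {
  g <- expr$table
  tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  prom <- tibble::tibble(
    chrom = g$chrom,
    start = pmax(0, ifelse(g$strand == "+", g$start - 2000, g$end)),
    end = ifelse(g$strand == "+", g$start, pmin(g$end + 2000, config$chrom_length))
  )
  first_exon <- tibble::tibble(
    chrom = g$chrom,
    start = ifelse(g$strand == "+", g$start, g$end - 200),
    end = ifelse(g$strand == "+", g$start + 200, g$end)
  )
  # three exons evenly placed in each gene body
  exon_at <- function(frac) {
    tibble::tibble(
      chrom = g$chrom,
      start = round(g$start + frac * (g$end - g$start - 200)),
      end = round(g$start + frac * (g$end - g$start - 200)) + 200
    )
  }
  exons <- dplyr::bind_rows(exon_at(0), exon_at(0.5), exon_at(0.95))
  introns <- tibble::tibble(
    chrom = g$chrom, start = g$start + 200, end = pmax(g$start + 201, g$end - 400)
  )
  five_utr <- tibble::tibble(
    chrom = g$chrom,
    start = ifelse(g$strand == "+", g$start, g$end - 100),
    end = ifelse(g$strand == "+", g$start + 100, g$end)
  )
  three_utr <- tibble::tibble(
    chrom = g$chrom,
    start = ifelse(g$strand == "+", g$end - 200, g$start),
    end = ifelse(g$strand == "+", g$end, g$start + 200)
  )
  cds <- tibble::tibble(chrom = g$chrom, start = g$start + 100, end = g$end - 200)
  n_enh <- config$n_genes
  enh_start <- floor(runif(n_enh, 0, config$chrom_length - 500))
  enhancer <- tibble::tibble(
    chrom = sample(sim_chroms(config), n_enh, replace = TRUE),
    start = enh_start, end = enh_start + 500
  )
  has_cgi <- runif(nrow(g)) < 0.6
  cgi <- tibble::tibble(
    chrom = g$chrom[has_cgi],
    start = pmax(0, tss[has_cgi] - 150),
    end = tss[has_cgi] + 150
  )
  shore <- dplyr::bind_rows(
    dplyr::mutate(cgi, end = .data$start, start = pmax(0, .data$start - 2000)),
    dplyr::mutate(cgi, start = .data$end, end = .data$end + 2000)
  )
  shelf <- dplyr::bind_rows(
    dplyr::mutate(cgi, end = pmax(0, .data$start - 2000), start = pmax(0, .data$start - 4000)),
    dplyr::mutate(cgi, start = .data$end + 2000, end = .data$end + 4000)
  )
  lnc_idx <- which(runif(nrow(g)) < 0.1)
  lncrna <- tibble::tibble(
    chrom = g$chrom[lnc_idx], start = g$start[lnc_idx], end = g$end[lnc_idx]
  )
  genic <- dplyr::bind_rows(
    tibble::tibble(chrom = g$chrom, start = g$start, end = g$end),
    prom, enhancer
  )
  intergenic <- complement_intervals(genic, sim_chrom_sizes(config))
  ann <- list(
    promoter = prom, first_exon = first_exon, exon = exons, intron = introns,
    five_utr = five_utr, three_utr = three_utr, cds = cds, enhancer = enhancer,
    cpg_island = cgi, cpg_shore = shore, cpg_shelf = shelf, lncrna = lncrna,
    intergenic = intergenic
  )
  lapply(ann, function(a) {
    a <- a[a$end > a$start & a$start >= 0, , drop = FALSE]
    a$end <- pmin(a$end, config$chrom_length)
    dplyr::arrange(a, .data$chrom, .data$start)
  })
}

#' Complement of a set of intervals within chromosome bounds
#'
#' @param intervals Tibble of `chrom`, `start`, `end` (0-based half-open).
#' @param chrom_sizes Chromosome sizes (data frame or named vector).
#' @return The uncovered intervals as a tibble.
#' @export
complement_intervals <- function(intervals, chrom_sizes) {
  cs <- as_chrom_sizes(chrom_sizes)
  gr <- GenomicRanges::reduce(intervals_to_granges(intervals))
  out <- list()
  for (i in seq_len(nrow(cs))) {
    ch <- cs$chrom[i]
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    cov_start <- GenomicRanges::start(sub) - 1L
    cov_end <- GenomicRanges::end(sub)
    pts <- sort(unique(c(0, cov_start, cov_end, cs$size[i])))
    gaps_start <- c(0, cov_end)
    gaps_end <- c(cov_start, cs$size[i])
    keep <- gaps_end > gaps_start
    out[[ch]] <- tibble::tibble(
      chrom = ch, start = gaps_start[keep], end = gaps_end[keep]
    )
  }
  dplyr::bind_rows(out)
}

# --- loops ----------------------------------------------------------------

sim_loops <- function(config, tads, borders) {
  conds <- config$conditions
  anchor_w <- 5000
  candidates <- with_stream(config$seed, "loop_candidates", {
    n <- config$n_loops
    chrom <- sample(sim_chroms(config), n, replace = TRUE)
    d <- round(sample_power_law(n, config$decay_exponent, 2e4, 2e6) / 1000) * 1000
    a1 <- floor(runif(n, 0, config$chrom_length - d - anchor_w) / 1000) * 1000
    tibble::tibble(
      chrom1 = chrom, start1 = a1, end1 = a1 + anchor_w,
      chrom2 = chrom, start2 = a1 + d, end2 = a1 + d + anchor_w,
      dist = d
    )
  })
  diff_idx <- with_stream(config$seed, "diff_loops", {
    idx <- sample.int(nrow(candidates), config$n_diff_loops)
    fav <- sample(conds, config$n_diff_loops, replace = TRUE)
    tibble::tibble(idx = idx, favored = fav)
  })

  base_lambda <- candidates$dist^(-config$decay_exponent)
  mid1 <- (candidates$start1 + candidates$end1) / 2
  mid2 <- (candidates$start2 + candidates$end2) / 2

  sets <- list()
  for (cond in conds) {
    td <- tads[[cond]]
    t1 <- tad_id_at(candidates$chrom1, mid1, td)
    t2 <- tad_id_at(candidates$chrom2, mid2, td)
    same_tad <- t1 > 0 & t1 == t2
    nb <- near_border(candidates$chrom1, mid1, borders[[cond]]) &
      near_border(candidates$chrom2, mid2, borders[[cond]])
    lam <- base_lambda
    lam[same_tad] <- lam[same_tad] * config$intra_tad_enrichment
    lam[nb] <- lam[nb] * config$border_loop_enrichment
    fav_here <- diff_idx$idx[diff_idx$favored == cond]
    lam[fav_here] <- lam[fav_here] * config$diff_loop_fold
    lam <- lam * config$read_depth / sum(lam)
    # decay-only background at the same total depth, for q-value calibration
    lam0 <- base_lambda * config$read_depth / sum(base_lambda)
    score <- with_stream(config$seed, paste0("loops_", cond), rpois(length(lam), lam))
    pval <- ppois(score - 1, lam0, lower.tail = FALSE)
    qval <- p.adjust(pval, method = "BH")
    sets[[cond]] <- loop_set(
      tibble::tibble(
        chrom1 = candidates$chrom1, start1 = candidates$start1, end1 = candidates$end1,
        chrom2 = candidates$chrom2, start2 = candidates$start2, end2 = candidates$end2,
        name = paste0("loop", seq_len(nrow(candidates))),
        score = score, q = signif(qval, 6), pets = score
      ),
      condition = cond,
      total_valid_pairs = sum(score)
    )
  }
  diff_loops <- dplyr::bind_cols(
    candidates[diff_idx$idx, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")],
    tibble::tibble(
      favored = diff_idx$favored, fold = config$diff_loop_fold,
      name = paste0("loop", diff_idx$idx)
    )
  )
  list(sets = sets, diff_loops = diff_loops)
}

# --- output writing -------------------------------------------------------

write_sim_outputs <- function(config, data, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), paste("cannot create output directory", out_dir))
  files <- character(0)
  p <- file.path(out_dir, "chrom.sizes")
  write_chrom_sizes(data$chrom_sizes, p)
  files <- c(files, p)
  ann_dir <- file.path(out_dir, "annotations")
  dir.create(ann_dir, showWarnings = FALSE)
  for (nm in names(data$annotations)) {
    p <- file.path(ann_dir, paste0(nm, ".bed"))
    write_bed(data$annotations[[nm]], p)
    files <- c(files, p)
  }
  peak_dir <- file.path(out_dir, "peaks")
  dir.create(peak_dir, showWarnings = FALSE)
  for (nm in names(data$peaks)) {
    p <- file.path(peak_dir, paste0(nm, ".narrowPeak"))
    write_narrowpeak(data$peaks[[nm]], p)
    files <- c(files, p)
  }
  loop_dir <- file.path(out_dir, "loops")
  dir.create(loop_dir, showWarnings = FALSE)
  for (nm in names(data$loops)) {
    p <- file.path(loop_dir, paste0(nm, ".bedpe"))
    write_bedpe(data$loops[[nm]], p)
    files <- c(files, p)
  }
  p <- file.path(out_dir, "expression.tsv")
  write_tsv_plain(data$expression, p)
  files <- c(files, p)
  p <- file.path(out_dir, "go_labels.tsv")
  write_tsv_plain(data$go_labels, p)
  files <- c(files, p)
  files
}

#' Simulate 40 kb contact matrices with planted TAD blocks
#'
#' Expected counts follow the configured power-law distance decay,
#' multiplied by `intra_tad_enrichment` when both bins fall inside the same
#' planted TAD of that condition; cells are independent Poisson draws on the
#' upper triangle, mirrored to give an exactly symmetric matrix. The total
#' expected mass per chromosome is `read_depth`.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_genome()] (needs `tads`).
#' @param bin Bin width in bp; must divide `chrom_length`.
#' @return Named list per condition of named lists per chromosome of
#'   symmetric matrices.
#' @export
simulate_contact_matrix <- function(config, truth, bin = 40000) {
  assert_that(config$chrom_length %% bin == 0,
    "`bin` must divide the chromosome length")
  n <- config$chrom_length / bin
  mid <- (seq_len(n) - 0.5) * bin
  out <- list()
  for (cond in config$conditions) {
    td <- truth$tads[[cond]]
    mats <- list()
    for (ch in sim_chroms(config)) {
      tid <- tad_id_at(rep(ch, n), mid, td[td$chrom == ch, , drop = FALSE])
      dmat <- abs(outer(seq_len(n), seq_len(n), "-"))
      lam <- (dmat + 1)^(-config$decay_exponent)
      same <- outer(tid, tid, function(a, b) a > 0 & a == b)
      lam[same] <- lam[same] * config$intra_tad_enrichment
      tot <- sum(lam[upper.tri(lam, diag = TRUE)])
      lam <- lam * config$read_depth / tot
      m <- with_stream(config$seed, paste0("matrix_", cond, "_", ch), {
        ut <- which(upper.tri(lam, diag = TRUE))
        v <- rpois(length(ut), lam[ut])
        mm <- matrix(0, n, n)
        mm[ut] <- v
        mm <- mm + t(mm)
        diag(mm) <- diag(mm) / 2
        mm
      })
      mats[[ch]] <- m
    }
    out[[cond]] <- mats
  }
  out
}
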