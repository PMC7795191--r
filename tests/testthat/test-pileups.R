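make_bins_with_signal <- function(sizes, width = 1000, fill = 0) {
  b <- bin_genome(sizes, width)
  b$sig <- rep(fill, nrow(b))
  b
}

test_that("midpoint alignment places signal at the right offsets", {
  b <- make_bins_with_signal(c(chr1 = 200000))
  mp <- tibble::tibble(chrom = "chr1", pos = 100500)
  flat <- pileup_colmeans(align_midpoints(b, "sig", mp, flank = 50000))
  expect_true(all(flat$mean == 0))
  # constant signal gives flat column means
  b2 <- make_bins_with_signal(c(chr1 = 200000), fill = 3)
  cm <- pileup_colmeans(align_midpoints(b2, "sig", mp, flank = 50000))
  expect_true(all(cm$mean == 3))
  # a delta spike 10 kb downstream appears only in that column
  b3 <- make_bins_with_signal(c(chr1 = 200000))
  b3$sig[b3$start == 110000] <- 9 # midpoint bin is [100000,101000)
  cm3 <- pileup_colmeans(align_midpoints(b3, "sig", mp, flank = 50000))
  expect_equal(cm3$mean[cm3$offset == 10000], 9)
  expect_equal(sum(cm3$mean != 0), 1)
  expect_error(align_midpoints(b, "sig", mp[0, ], flank = 1000), "empty")
})

test_that("mirrored signal yields exactly mirrored column means", {
  set.seed(31)
  b <- make_bins_with_signal(c(chr1 = 100000))
  half <- rpois(20, 5)
  center_bin <- 50 # bin [49000,50000); midpoint at 49500
  b$sig[(center_bin - 20):(center_bin - 1)] <- half
  b$sig[(center_bin + 1):(center_bin + 20)] <- rev(half)
  mp <- tibble::tibble(chrom = "chr1", pos = 49500)
  cm <- pileup_colmeans(align_midpoints(b, "sig", mp, flank = 25000))
  # column at +k bp mirrors column at -k bp around the center bin
  plus <- cm$mean[cm$offset >= 1000 & cm$offset <= 20000]
  minus <- cm$mean[cm$offset <= -1000 & cm$offset >= -20000]
  expect_identical(plus, rev(minus))
})

test_that("orientation flip is an involution and summaries skip masked cells", {
  set.seed(8)
  v <- matrix(rnorm(60), 6, 10)
  mask <- matrix(runif(60) < 0.3, 6, 10)
  pu <- pileup_matrix(v, offsets = (0:9) * 1000, bin = 1000, mask = mask)
  flipped_twice <- flip_pileup_rows(flip_pileup_rows(pu, c(2, 5)), c(2, 5))
  expect_identical(flipped_twice$values, pu$values)
  expect_identical(flipped_twice$mask, pu$mask)
  # sentinel values under the mask never leak into any summary
  poisoned <- pu
  poisoned$values[poisoned$mask] <- 1e12
  clean <- pu
  clean$values[clean$mask] <- 0
  expect_equal(pileup_colmeans(poisoned)$mean, pileup_colmeans(clean)$mean)
  expect_equal(pileup_rowmeans(poisoned)$mean, pileup_rowmeans(clean)$mean)
})

test_that("pile-up summaries are invariant to input locus order", {
  set.seed(9)
  b <- make_bins_with_signal(c(chr1 = 500000))
  b$sig <- rpois(nrow(b), 4)
  mp <- tibble::tibble(chrom = "chr1", pos = c(100500, 250500, 400500))
  cm1 <- pileup_colmeans(align_midpoints(b, "sig", mp, flank = 50000))
  cm2 <- pileup_colmeans(align_midpoints(b, "sig", mp[c(3, 1, 2), ],
    flank = 50000))
  expect_equal(cm1, cm2)
})

test_that("TAD overlap profile counts covered loci per offset", {
  mp <- tibble::tibble(chrom = "chr1", pos = c(1e6, 3e6))
  cover_all <- tad_set(tibble::tibble(chrom = "chr1", start = 0, end = 5e6))
  prof <- tad_overlap_profile(mp, cover_all, flank = 100000, bin = 10000)
  expect_true(all(prof$count == 2))
  none <- tad_set(tibble::tibble(chrom = "chr2", start = 0, end = 1e6))
  expect_true(all(tad_overlap_profile(mp, none, flank = 1e5, bin = 1e4)$count == 0))
  # one TAD spanning [-100 kb, +50 kb] of the first locus only
  one <- tad_set(tibble::tibble(chrom = "chr1", start = 9e5, end = 1.05e6))
  p1 <- tad_overlap_profile(mp[1, ], one, flank = 100000, bin = 10000)
  expect_equal(p1$count, as.integer(p1$offset >= -100000 & p1$offset < 50000))
})

test_that("DiffTAD orientation follows regulated-gene directionality", {
  tads <- tad_set(tibble::tibble(chrom = "chr1", start = c(0, 3e5, 6e5),
    end = c(3e5, 6e5, 9e5)))
  expr <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    chrom = "chr1", start = c(1e5, 4e5, 4.5e5),
    end = c(1.5e5, 4.4e5, 4.6e5),
    strand = c("+", "-", "-"),
    log2fc = c(2, 3, 3), q = c(0.01, 0.01, 0.01)
  )
  od <- orient_difftads(tads, expr, "up")
  expect_equal(od$orientation, c(1, -1, 1))
  expect_equal(od$default_orientation, c(FALSE, FALSE, TRUE))
  # downregulated direction ignores upregulated genes
  od_down <- orient_difftads(tads, expr, "down")
  expect_true(all(od_down$default_orientation))
})

test_that("border alignment masks past TAD midpoints and flips reversed TADs", {
  b <- make_bins_with_signal(c(chr1 = 1e6))
  # marker 10 kb inside the left border of a forward TAD
  tad_fwd <- tibble::tibble(chrom = "chr1", start = 3e5, end = 5e5,
    orientation = 1, default_orientation = FALSE)
  b$sig[b$start == 310000] <- 5
  al <- align_tad_borders(tad_fwd, b, "sig", flank = 150000)
  cmL <- pileup_colmeans(al$left)
  expect_equal(cmL$mean[cmL$offset == 10000], 5)
  # left pile-up masks offsets past the 100 kb midpoint of a 200 kb TAD
  expect_true(all(al$left$mask[1, al$left$offsets + 500 > 100000]))
  expect_false(any(al$left$mask[1, al$left$offsets + 500 < 100000 &
    al$left$offsets >= -150000]))
  # reversing the orientation mirrors the marker to the right-border role:
  # reading from the physical end leftward, the marker sits 190 kb inward
  tad_rev <- tad_fwd
  tad_rev$orientation <- -1
  al_rev <- align_tad_borders(tad_rev, b, "sig", flank = 150000)
  cmL_rev <- pileup_colmeans(al_rev$left)
  # from the flipped left origin (physical end 5e5) the marker at 310 kb is
  # 190 kb inward, beyond the flank, so the left view no longer sees it
  expect_true(all(cmL_rev$mean == 0 | is.na(cmL_rev$mean)))
  cmR_rev <- pileup_colmeans(al_rev$right)
  # the right border role falls on the physical start; reading outward
  # (orientation -1) the marker appears at offset -10 kb... masked past the
  # midpoint rule does not apply at -10 kb (inside, within half length)
  expect_equal(cmR_rev$mean[cmR_rev$offset == -11000], 5)
})

test_that("manual flip oracle: minus-strand TADs mirror a border marker", {
  b <- make_bins_with_signal(c(chr1 = 2e6))
  tads <- tad_set(tibble::tibble(
    chrom = "chr1", start = c(1e5, 6e5, 11e5), end = c(4e5, 9e5, 14e5)
  ))
  # markers 20 kb inside each left border
  b$sig[b$start %in% (tads$start + 20000)] <- 7
  expr <- tibble::tibble(
    gene_id = paste0("g", 1:3), chrom = "chr1",
    start = tads$start + 50000, end = tads$start + 60000,
    strand = c("+", "+", "-"), log2fc = 2, q = 0.001
  )
  od <- orient_difftads(tads, expr, "up")
  expect_equal(od$orientation, c(1, 1, -1))
  al <- align_tad_borders(od, b, "sig", flank = 100000)
  cm <- pileup_colmeans(al$left)
  # forward TADs put the marker at +20 kb of the left border; the flipped
  # TAD reads from its physical right border inward, where the marker sits
  # at 280 kb, outside the flank: mean at +20 kb is 2 hits out of 3 loci
  expect_equal(cm$mean[cm$offset == 20000], 14 / 3)
  # the flipped TAD's right-border view sees the marker at -21 kb
  cmR <- pileup_colmeans(al$right)
  expect_equal(cmR$mean[cmR$offset == -21000], 7 / 3)
})

test_that("same-size stacking recovers trivial and planted correlations", {
  set.seed(17)
  n_tads <- 40
  size <- 480000
  b <- bin_genome(c(chr1 = n_tads * size), 10000)
  tads <- tad_set(tibble::tibble(
    chrom = "chr1", start = (0:(n_tads - 1)) * size,
    end = (1:n_tads) * size
  ))
  per_tad <- runif(n_tads, 1, 10)
  b$anchor_strength <- rep(per_tad, each = size / 10000) +
    rnorm(nrow(b), 0, 0.01)
  b$same <- b$anchor_strength
  b$anti <- -b$anchor_strength
  st <- stack_same_size(tads, b, attrs = c("same", "anti"),
    n = n_tads, size = size)
  expect_equal(st$correlations$r[st$correlations$attr == "same"], 1,
    tolerance = 1e-6)
  expect_equal(st$correlations$r[st$correlations$attr == "anti"], -1,
    tolerance = 1e-6)
  # rows are sorted by decreasing mean sort attribute
  key <- rowMeans(st$pileups$anchor_strength$values)
  expect_true(all(diff(key) <= 1e-9))
  expect_error(stack_same_size(tads, b, attrs = "same", n = 500), "found")
})

test_that("planted attribute-strength coupling of 0.8 is recovered across seeds", {
  n_tads <- 200
  size <- 480000
  bins_w <- 40000
  rs <- vapply(1:20, function(seed) {
    set.seed(seed)
    b <- bin_genome(c(chr1 = n_tads * size), bins_w)
    tads <- tad_set(tibble::tibble(
      chrom = "chr1", start = (0:(n_tads - 1)) * size, end = (1:n_tads) * size
    ))
    strength <- rnorm(n_tads)
    # calibrate the TAD-level noise so the 5-TAD-binned statistic has a
    # population Pearson R of 0.8: binned signal sd comes from the sorted
    # block means, and block-mean noise is the TAD noise over sqrt(5)
    s_b <- colMeans(matrix(sort(strength, decreasing = TRUE), nrow = 5))
    sigma <- sqrt(5) * 0.8 * sd(s_b) * tan(acos(0.8))
    attrv <- 0.8 * strength + sigma * rnorm(n_tads)
    b$anchor_strength <- rep(strength, each = size / bins_w)
    b$coupled <- rep(attrv, each = size / bins_w)
    st <- stack_same_size(tads, b, attrs = "coupled", n = n_tads, size = size)
    st$correlations$r
  }, numeric(1))
  expect_equal(mean(rs), 0.8, tolerance = 0.07)
})

test_that("split alignment halves TADs and removes middles beyond 2 Mb", {
  b <- make_bins_with_signal(c(chr1 = 8e6), fill = 1)
  tads <- tad_set(tibble::tibble(
    chrom = "chr1", start = c(0, 1e6, 4e6), end = c(4e5, 1.4e6, 7e6)
  ))
  sp <- split_align_all(tads, b, "sig")
  # 400 kb TADs contribute 200 kb halves with no mask inside
  expect_equal(sum(!sp$left$mask[1, ]), 200)
  # the 3 Mb TAD contributes only its outer 1 Mb per side
  expect_equal(sum(!sp$left$mask[3, ]), 1000)
  expect_equal(sum(!sp$right$mask[3, ]), 1000)
  expect_equal(ncol(sp$left$values), 1000)
  # rows sorted by TAD length
  expect_equal(sp$left$rows$end - sp$left$rows$start, c(4e5, 4e5, 3e6))
})

test_that("border-enriched signal shows up at offset zero of split halves", {
  set.seed(23)
  cfg <- sim_config(n_chroms = 1, chrom_length = 8e6, seed = 23,
    n_peaks_per_protein = 800, border_peak_enrichment = 8)
  sim <- simulate_genome(cfg)
  b <- bin_genome(sim$data$chrom_sizes, 1000)
  b <- overlay_score(b, dplyr::mutate(sim$data$peaks$ctcf_ESC,
    score = .data$signalValue), "ctcf")
  tads <- tad_set(sim$truth$tads$ESC)
  sp <- split_align_all(tads, b, "ctcf")
  border_mean <- mean(sp$col_means$left$mean[1:2])
  interior_mean <- mean(sp$col_means$left$mean[20:40], na.rm = TRUE)
  expect_gt(border_mean, interior_mean)
})
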