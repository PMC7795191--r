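test_that("z-score profile reproduces the hand-computed spike case", {
  prof <- zscore_profile(c(0, 0, 0, 10))
  expect_equal(prof$z[4], 1.5)
  expect_equal(prof$p[4], 2 * pnorm(-1.5), tolerance = 1e-12)
  expect_equal(round(prof$p[4], 4), 0.1336)
  # constant profile: all p = 1
  flat <- zscore_profile(rep(4, 10))
  expect_true(all(flat$z == 0))
  expect_true(all(flat$p == 1))
  # two-tailed symmetry under negation
  x <- c(1, 5, 2, 8, 3)
  expect_equal(zscore_profile(-x)$p, zscore_profile(x)$p)
  expect_error(zscore_profile(c(1, 2)), "3 bins")
})

test_that("null z-score profiles flag about 5 percent of bins", {
  set.seed(19)
  flagged <- 0
  total <- 0
  for (rep in 1:20) {
    prof <- zscore_profile(rnorm(150))
    flagged <- flagged + sum(prof$p < 0.05)
    total <- total + nrow(prof)
  }
  expect_gte(flagged / total, 0.03)
  expect_lte(flagged / total, 0.07)
})

test_that("two-way ANOVA Tukey comparison flags shifted blocks", {
  set.seed(4)
  offs <- (0:24) * 1000
  a <- tibble::tibble(offset = offs, mean = rnorm(25, 10, 0.5))
  b <- a
  b$mean[6:10] <- b$mean[6:10] + 8 # second 5-bin block strongly shifted
  res <- compare_conditions_anova(a, b, k = 5)
  expect_equal(nrow(res), 5)
  expect_lt(res$p[2], 0.01)
  expect_gt(min(res$p[-2]), 0.05)
  # identical profiles: no signal
  same <- compare_conditions_anova(a, a, k = 5)
  expect_true(all(same$p == 1 | is.na(same$p)))
})

test_that("GO profiles are zero-centered and category-independent", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200),
    chrom = "chr1",
    start = seq(10000, 1990000, length.out = 200),
    end = seq(10000, 1990000, length.out = 200) + 1000,
    strand = "+"
  )
  centers <- tibble::tibble(chrom = "chr1", pos = 1e6)
  # category A clustered within +/-100 kb of the center, B uniform
  near <- abs(genes$start - 1e6) <= 1e5
  go <- tibble::tibble(
    gene_id = genes$gene_id,
    go_category = ifelse(near, "catA", "catB")
  )
  res <- go_positional_profile(genes, go, centers, flank = 1e6, bin = 1000)
  profA <- res$profiles[res$profiles$category == "catA", ]
  # zero-centering: profile sums to ~0 over the span
  expect_equal(sum(profA$centered), 0, tolerance = 1e-9)
  expect_gt(mean(profA$centered[abs(profA$offset) <= 1e5]), 0)
  expect_lt(mean(profA$centered[abs(profA$offset) > 2e5]), 0)
  # a uniformly spread category (one gene per bin) is flat at zero
  dense <- tibble::tibble(
    gene_id = sprintf("d%04d", 1:2000),
    chrom = "chr1", start = (0:1999) * 1000 + 100,
    end = (0:1999) * 1000 + 600, strand = "+"
  )
  uni <- tibble::tibble(gene_id = dense$gene_id, go_category = "only")
  res_u <- go_positional_profile(dense, uni, centers, flank = 1e6, bin = 1000)
  expect_true(all(abs(res_u$profiles$centered) < 1e-12))
  # categories are computed independently: restricting the map to one
  # category leaves that category's per-bin ratios unchanged (each bin
  # holds at most one gene here)
  solo <- go_positional_profile(genes, go[go$go_category == "catA", ],
    centers, flank = 1e6, bin = 1000)
  soloA <- solo$profiles[solo$profiles$category == "catA", ]
  sel <- profA$ratio > 0
  expect_equal(soloA$ratio[sel], profA$ratio[sel])
  expect_error(go_positional_profile(genes, go[0, ], centers), "empty")
})

test_that("DiffGene ranking matches the exhaustive oracle on small fixtures", {
  set.seed(27)
  for (rep in 1:25) {
    n_loops <- sample(5:50, 1)
    n_genes <- sample(5:40, 1)
    max_pos <- 5e6
    s1 <- sample(seq(0, max_pos - 1e6, by = 1000), n_loops, replace = TRUE)
    gap <- sample(seq(20000, 8e5, by = 1000), n_loops, replace = TRUE)
    loops <- loop_set(tibble::tibble(
      chrom1 = "chr1", start1 = s1, end1 = s1 + 10000,
      chrom2 = "chr1", start2 = s1 + gap, end2 = s1 + gap + 10000,
      score = 5, q = sample(c(1e-5, 0.5), n_loops, replace = TRUE)
    ))
    gs <- sample(seq(0, max_pos - 1e5, by = 500), n_genes)
    expr <- tibble::tibble(
      gene_id = sprintf("g%02d", seq_len(n_genes)),
      chrom = "chr1", start = gs, end = gs + sample(2000:50000, n_genes,
        replace = TRUE),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      log2fc = round(rnorm(n_genes, 0, 2), 3),
      q = 0.001
    )
    for (dir in c("up", "down")) {
      got <- rank_diffgenes(loops, expr, dir,
        q_max = 0.001, top_n = 10,
        min_spacing = 5e5
      )
      want <- oracle_rank_diffgenes(loops, expr, dir, 0.001, 10, 5e5)
      expect_equal(got$start1, loops$start1[want])
      expect_equal(nrow(got), length(want))
    }
  }
})

test_that("DiffGene spacing rule skips nearby candidates", {
  # three far-apart loops rank by their anchor log2FC sums
  mk_loop <- function(s) {
    c(start1 = s, end1 = s + 10000, start2 = s + 100000, end2 = s + 110000)
  }
  loops <- loop_set(tibble::tibble(
    chrom1 = "chr1", start1 = c(0, 10e6, 20e6),
    end1 = c(10000, 10e6 + 10000, 20e6 + 10000),
    chrom2 = "chr1", start2 = c(100000, 10.1e6, 20.1e6),
    end2 = c(110000, 10.1e6 + 10000, 20.1e6 + 10000),
    score = 5, q = 1e-5
  ))
  expr <- tibble::tibble(
    gene_id = c("a", "b", "c"), chrom = "chr1",
    start = c(1000, 10e6 + 1000, 20e6 + 1000),
    end = c(9000, 10e6 + 9000, 20e6 + 9000),
    strand = "+", log2fc = c(5.0, 3.2, 4.1), q = 0.001
  )
  got <- rank_diffgenes(loops, expr, "up", top_n = 3, min_spacing = 2.5e6)
  expect_equal(got$sum_log2fc, c(5.0, 4.1, 3.2))
  # move the second-best within 1 Mb of the best: it is skipped
  loops2 <- loops
  loops2$start1[3] <- 0.5e6
  loops2$end1[3] <- 0.51e6
  loops2$start2[3] <- 0.6e6
  loops2$end2[3] <- 0.61e6
  expr2 <- expr
  expr2$start[3] <- 0.501e6
  expr2$end[3] <- 0.509e6
  got2 <- rank_diffgenes(loops2, expr2, "up", top_n = 2, min_spacing = 2.5e6)
  expect_equal(got2$sum_log2fc, c(5.0, 3.2))
  expect_error(rank_diffgenes(filter_loops_q(loops, 1e-9), expr, "up"), "pass")
})

test_that("downregulated ranking reads fold changes in the opposite ratio", {
  loops <- loop_set(tibble::tibble(
    chrom1 = "chr1", start1 = 0, end1 = 10000,
    chrom2 = "chr1", start2 = 100000, end2 = 110000,
    score = 5, q = 1e-5
  ))
  expr <- tibble::tibble(
    gene_id = c("up_g", "down_g"), chrom = "chr1",
    start = c(1000, 101000), end = c(9000, 109000), strand = "+",
    log2fc = c(2, -3), q = 0.001
  )
  up <- rank_diffgenes(loops, expr, "up", top_n = 5)
  down <- rank_diffgenes(loops, expr, "down", top_n = 5)
  expect_equal(up$sum_log2fc, 2) # only the upregulated gene counts
  expect_equal(down$sum_log2fc, 3) # -(-3): the inverted ratio is positive
})
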