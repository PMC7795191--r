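test_that("hierarchical grid assigns loops to fine pairs by anchor midpoints", {
  expect_error(
    hierarchical_grid(random_loops(1, "chrA", 1000), c(chrA = 1e6), 300, 1000),
    "multiple"
  )
  cs <- c(chrA = 2e6)
  # a full coarse cell holds (coarse/fine)^2 fine pairs off-diagonal
  empty <- loop_set(tibble::tibble(chrom1 = character(), start1 = numeric(),
    end1 = numeric(), chrom2 = character(), start2 = numeric(),
    end2 = numeric(), score = numeric()))
  g0 <- hierarchical_grid(empty, cs, 1e5, 1e6)
  expect_true(all(g0$blocks$`chrA|chrA`$mat == 0))
  lp <- loop_set(tibble::tibble(
    chrom1 = "chrA", start1 = 145000, end1 = 155000,
    chrom2 = "chrA", start2 = 1245000, end2 = 1255000, score = 7
  ))
  g <- hierarchical_grid(lp, cs, 1e5, 1e6)
  mat <- g$blocks$`chrA|chrA`$mat
  expect_equal(sum(mat != 0), 1)
  # midpoints 150 kb and 1250 kb sit in fine bins 2 and 13
  expect_equal(mat[2, 13], 7)
})

test_that("paired t on a single cell matches the closed form", {
  mk_grid <- function(values, cond) {
    g <- hierarchical_grid(
      dense_grid_loops(values, 2, 1e5, condition = cond),
      c(chrA = 2e5), 1e5, 2e5
    )
    g
  }
  # fine values laid on the 2x2 upper triangle: (1,1),(1,2),(2,2) plus the
  # inter pair; use an explicit 2x2 block via the region scope instead
  region_grid <- function(m, cond) {
    lp <- loop_set(tibble::tibble(
      chrom1 = "chrA", start1 = c(0, 0, 1, 1) * 1000 + 100,
      end1 = c(0, 0, 1, 1) * 1000 + 200,
      chrom2 = "chrA", start2 = c(2, 3, 2, 3) * 1000 + 100,
      end2 = c(2, 3, 2, 3) * 1000 + 200,
      score = as.vector(m)
    ), condition = cond)
    hierarchical_grid(lp, c(chrA = 4e3), 1000, 2000)
  }
  ga <- region_grid(c(1, 3, 2, 4), "A")
  gb <- region_grid(c(3, 5, 3, 6), "B")
  tt <- paired_t_grid(ga, gb)
  cell <- tt[tt$cell1_start == 0 & tt$cell2_start == 2000, ]
  expect_equal(cell$n, 4L)
  expect_equal(cell$mean_delta, 1.75)
  expect_equal(cell$t, 7)
  expect_equal(cell$df, 3)
  expect_equal(cell$p, 2 * pt(-7, 3), tolerance = 1e-12)
  expect_equal(cell$favored, "B")
  # identical inputs: p = 1 everywhere, delta 0
  same <- paired_t_grid(ga, ga)
  expect_true(all(same$p == 1))
  expect_true(all(same$mean_delta == 0))
  # swapping conditions negates t and delta, p unchanged
  rev_tt <- paired_t_grid(gb, ga)
  cell_r <- rev_tt[rev_tt$cell1_start == 0 & rev_tt$cell2_start == 2000, ]
  expect_equal(cell_r$t, -cell$t)
  expect_equal(cell_r$mean_delta, -cell$mean_delta)
  expect_equal(cell_r$p, cell$p)
})

test_that("grid t statistics match t.test on 1000 random cells", {
  set.seed(21)
  n_fine <- 100 # 10 coarse bins -> 55 cells per round
  fine <- 1e4
  cs <- c(chrA = n_fine * fine)
  n_pairs <- n_fine * (n_fine + 1) / 2
  checked <- 0
  round <- 0
  while (checked < 1000) {
    round <- round + 1
    va <- rpois(n_pairs, 5)
    vb <- rpois(n_pairs, 5)
    ga <- hierarchical_grid(dense_grid_loops(va, n_fine, fine, condition = "A"),
      cs, fine, 1e5)
    gb <- hierarchical_grid(dense_grid_loops(vb, n_fine, fine, condition = "B"),
      cs, fine, 1e5)
    tt <- paired_t_grid(ga, gb)
    # oracle: reconstruct each cell's paired vectors and run t.test
    ma <- ga$blocks$`chrA|chrA`$mat
    mb <- gb$blocks$`chrA|chrA`$mat
    for (r in seq_len(nrow(tt))) {
      i_range <- (tt$cell1_start[r] / fine + 1):(tt$cell1_end[r] / fine)
      j_range <- (tt$cell2_start[r] / fine + 1):(tt$cell2_end[r] / fine)
      sel <- as.matrix(expand.grid(i = i_range, j = j_range))
      sel <- sel[sel[, 1] <= sel[, 2], , drop = FALSE]
      da <- ma[sel]
      db <- mb[sel]
      if (sd(db - da) == 0) next
      ref <- t.test(db, da, paired = TRUE)
      expect_equal(tt$t[r], unname(ref$statistic), tolerance = 1e-9)
      expect_equal(tt$p[r], ref$p.value, tolerance = 1e-9)
      checked <- checked + 1
    }
    if (round > 30) break
  }
  expect_gte(checked, 1000)
})

test_that("degenerate cells are flagged and all-zero cells give p = 1", {
  lp0 <- dense_grid_loops(rep(0, 3), 2, 1000, condition = "A")
  ga <- hierarchical_grid(lp0, c(chrA = 2000), 1000, 2000)
  gb <- hierarchical_grid(dense_grid_loops(c(2, 2, 2), 2, 1000, condition = "B"),
    c(chrA = 2000), 1000, 2000)
  same <- paired_t_grid(ga, ga)
  expect_true(all(same$p == 1))
  expect_false(any(same$degenerate))
  deg <- paired_t_grid(ga, gb)
  expect_true(all(deg$degenerate))
  expect_true(all(deg$p == 0))
})

test_that("differential loop rendering splits by favored condition with the max rule", {
  region_grid <- function(scores, cond) {
    hierarchical_grid(dense_grid_loops(scores, 6, 1e4, condition = cond),
      c(chrA = 6e4), 1e4, 2e4)
  }
  n_pairs <- 6 * 7 / 2
  base <- rep(4, n_pairs)
  ga <- region_grid(base, "A")
  gb0 <- region_grid(base, "B")
  none <- differential_loops(paired_t_grid(ga, gb0))
  expect_equal(nrow(none$A), 0)
  expect_equal(nrow(none$B), 0)
  # push one cell up for B
  vb <- base
  vb[1:3] <- 12
  gb <- region_grid(vb, "B")
  both <- differential_loops(paired_t_grid(ga, gb))
  expect_gt(nrow(both$B), 0)
  expect_equal(nrow(both$A), 0)
  # two cells sharing a midpoint: statistic annotated only on the max delta
  tests <- tibble::tibble(
    chrom1 = "chrA", cell1_start = c(0, 10000), cell1_end = c(10000, 20000),
    chrom2 = "chrA", cell2_start = c(40000, 30000), cell2_end = c(50000, 40000),
    n = 4L, mean_a = 1, mean_b = c(4, 2), mean_delta = c(3, 1),
    t = 5, df = 3, p = 0.01, degenerate = FALSE, p_adj = 0.01,
    favored = "B"
  )
  attr(tests, "conditions") <- c("A", "B")
  class(tests) <- c("paired_grid_tests", class(tests))
  out <- differential_loops(tests)
  expect_equal(out$B$stat_shown, c(TRUE, FALSE))
  expect_equal(out$B$mean_delta[out$B$stat_shown], 3)
})

test_that("midpoint truncation removes loops reaching past their TAD midpoint", {
  tads <- tad_set(tibble::tibble(chrom = "chrA", start = 0, end = 200000))
  tests <- tibble::tibble(
    chrom1 = "chrA",
    cell1_start = c(10000, 10000), cell1_end = c(20000, 20000),
    chrom2 = "chrA",
    cell2_start = c(60000, 150000), cell2_end = c(70000, 160000),
    n = 4L, mean_a = 1, mean_b = 2, mean_delta = 1, t = 2, df = 3,
    p = 0.1, degenerate = FALSE, p_adj = 0.1, favored = "B"
  )
  attr(tests, "conditions") <- c("A", "B")
  class(tests) <- c("paired_grid_tests", class(tests))
  kept <- truncate_past_tad_midpoint(tests, tads)
  # the loop ending at 155 kb crosses the 100 kb TAD midpoint and is dropped
  expect_equal(nrow(kept), 1)
  expect_equal(kept$cell2_start, 60000)
  expect_error(differential_loops(tests, truncate = TRUE), "context")
})

test_that("network metrics match brute force and igraph on fixed graphs", {
  star <- tibble::tibble(from = "hub", to = paste0("leaf", 1:4))
  net <- network_from_edges(star)
  expect_equal(net$nodes$degree[net$nodes$node == "hub"], 4)
  expect_true(all(net$nodes$clustering == 0))
  tri <- tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "a"))
  net_tri <- network_from_edges(tri)
  expect_true(all(net_tri$nodes$degree == 2))
  expect_true(all(net_tri$nodes$clustering == 1))
  # Erdos-Renyi graph against the adjacency oracle and igraph
  set.seed(13)
  n <- 50
  pairs <- t(combn(n, 2))
  sel <- pairs[runif(nrow(pairs)) < 0.2, ]
  edges <- tibble::tibble(
    from = sprintf("n%02d", sel[, 1]),
    to = sprintf("n%02d", sel[, 2])
  )
  net_er <- network_from_edges(edges)
  oracle <- oracle_network_metrics(edges)
  expect_equal(net_er$nodes$node, oracle$nodes)
  expect_equal(unname(net_er$nodes$degree), unname(oracle$degree))
  expect_equal(unname(net_er$nodes$clustering), unname(oracle$clustering))
  skip_if_not_installed("igraph")
  ig <- igraph::graph_from_data_frame(edges, directed = FALSE)
  deg_ig <- igraph::degree(ig)[net_er$nodes$node]
  cc_ig <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
  names(cc_ig) <- igraph::V(ig)$name
  expect_equal(unname(net_er$nodes$degree), unname(deg_ig))
  expect_equal(unname(net_er$nodes$clustering), unname(cc_ig[net_er$nodes$node]))
})

test_that("top-n selection ranks by favored-condition strength and clamps", {
  tests <- tibble::tibble(
    chrom1 = "chrA", cell1_start = (0:4) * 1e6, cell1_end = (1:5) * 1e6,
    chrom2 = "chrA", cell2_start = (5:9) * 1e6, cell2_end = (6:10) * 1e6,
    n = 100L, mean_a = 1, mean_b = c(5, 4, 3, 2, 0.5),
    mean_delta = c(4, 3, 2, 1, -0.5), t = 2, df = 99, p = 0.01,
    degenerate = FALSE, p_adj = 0.01,
    favored = c("B", "B", "B", "B", "A")
  )
  attr(tests, "conditions") <- c("A", "B")
  class(tests) <- c("paired_grid_tests", class(tests))
  net <- top_n_network(tests, n = 2, condition = "B")
  expect_equal(nrow(net$edges), 2)
  expect_equal(sort(net$edges$weight, decreasing = TRUE), c(5, 4))
  expect_warning(top_n_network(tests, n = 100, condition = "B"), "clamped")
  # strength filter removes the >1 cells
  net_f <- top_n_network(tests, n = 10, condition = "B",
    max_mean_strength = 3.5) |> suppressWarnings()
  expect_true(all(net_f$edges$weight <= 3.5))
})
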