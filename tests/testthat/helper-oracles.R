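# Independent brute-force oracles and tiny fixture builders. Every oracle
# works per-bp or per-element and never shares code with the implementation.

# per-bp oracle for score overlays: full interval score added to every bin
# the interval touches (no proration)
oracle_overlay_score <- function(bins, intervals) {
  vapply(seq_len(nrow(bins)), function(i) {
    total <- 0
    for (k in seq_len(nrow(intervals))) {
      if (intervals$chrom[k] != bins$chrom[i]) next
      bps <- seq(intervals$start[k], intervals$end[k] - 1)
      if (any(bps >= bins$start[i] & bps < bins$end[i])) {
        total <- total + intervals$score[k]
      }
    }
    total
  }, numeric(1))
}

# per-bp oracle for span overlays: overlap base pairs summed then capped
oracle_overlay_span <- function(bins, intervals, cap) {
  vapply(seq_len(nrow(bins)), function(i) {
    bp <- 0
    for (k in seq_len(nrow(intervals))) {
      if (intervals$chrom[k] != bins$chrom[i]) next
      bps <- seq(intervals$start[k], intervals$end[k] - 1)
      bp <- bp + sum(bps >= bins$start[i] & bps < bins$end[i])
    }
    min(bp, cap)
  }, numeric(1))
}

# both-anchor oracle for anchor strength
oracle_anchor_strength <- function(bins, loops) {
  vapply(seq_len(nrow(bins)), function(i) {
    total <- 0
    for (k in seq_len(nrow(loops))) {
      for (a in 1:2) {
        ch <- loops[[paste0("chrom", a)]][k]
        s <- loops[[paste0("start", a)]][k]
        e <- loops[[paste0("end", a)]][k]
        if (ch != bins$chrom[i]) next
        bps <- seq(s, e - 1)
        if (any(bps >= bins$start[i] & bps < bins$end[i])) {
          total <- total + loops$score[k]
        }
      }
    }
    total
  }, numeric(1))
}

# brute-force window-sum oracle for two-window features (one chromosome)
oracle_two_window <- function(values, bin_width, window) {
  k <- window / bin_width
  left <- ceiling(k / 2) - 1
  vapply(seq_along(values), function(i) {
    from <- i - left
    to <- from + k - 1
    if (from < 1 || to > length(values)) {
      return(NA_real_)
    }
    sum(values[from:to]) / window
  }, numeric(1))
}

# exhaustive ranking + greedy-spacing oracle for DiffGene selection
oracle_rank_diffgenes <- function(loops, expression, direction, q_max,
                                  top_n, min_spacing) {
  sgn <- if (direction == "up") 1 else -1
  sums <- numeric(nrow(loops))
  for (i in seq_len(nrow(loops))) {
    for (g in seq_len(nrow(expression))) {
      if (sign(expression$log2fc[g]) != sgn) next
      for (a in 1:2) {
        ch <- loops[[paste0("chrom", a)]][i]
        s <- loops[[paste0("start", a)]][i]
        e <- loops[[paste0("end", a)]][i]
        if (expression$chrom[g] == ch &&
          expression$start[g] < e && expression$end[g] > s) {
          sums[i] <- sums[i] + sgn * expression$log2fc[g]
        }
      }
    }
  }
  mids <- ((loops$start1 + loops$end1) / 2 + (loops$start2 + loops$end2) / 2) / 2
  keep <- which(!is.na(loops$q) & loops$q < q_max & sums > 0)
  ord <- keep[order(-sums[keep], loops$chrom1[keep], loops$start1[keep],
    loops$start2[keep])]
  picked <- integer(0)
  for (i in ord) {
    if (length(picked) >= top_n) break
    same <- picked[loops$chrom1[picked] == loops$chrom1[i]]
    if (length(same) == 0 || min(abs(mids[same] - mids[i])) >= min_spacing) {
      picked <- c(picked, i)
    }
  }
  picked
}

# adjacency-matrix oracle for degree and local clustering
oracle_network_metrics <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    if (edges$from[k] == edges$to[k]) next
    A[edges$from[k], edges$to[k]] <- 1
    A[edges$to[k], edges$from[k]] <- 1
  }
  deg <- rowSums(A)
  cc <- vapply(seq_along(nodes), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) {
      return(0)
    }
    links <- sum(A[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, numeric(1))
  list(nodes = nodes, degree = deg, clustering = cc)
}

# random small-genome fixtures
random_intervals <- function(n, chroms, max_pos, max_score = 10) {
  start <- sample.int(max_pos - 100, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(500, n, replace = TRUE),
    score = sample.int(max_score, n, replace = TRUE)
  )
}

random_loops <- function(n, chroms, max_pos) {
  stopifnot(max_pos >= 300)
  w <- min(500, max_pos %/% 3)
  s1 <- sample.int(max_pos - w, n, replace = TRUE)
  s2 <- sample.int(max_pos - w, n, replace = TRUE)
  ch <- sample(chroms, n, replace = TRUE)
  loop_set(tibble::tibble(
    chrom1 = ch, start1 = s1, end1 = s1 + sample.int(w, n, replace = TRUE),
    chrom2 = ch, start2 = s2, end2 = s2 + sample.int(w, n, replace = TRUE),
    score = sample.int(20, n, replace = TRUE),
    q = runif(n)
  ))
}

# dense loop set assigning one loop per fine pair of a K-coarse-bin
# chromosome; scores supplied per fine pair (upper triangle order)
dense_grid_loops <- function(scores, n_fine, fine, chrom = "chrA",
                             condition = "A") {
  idx <- which(upper.tri(matrix(0, n_fine, n_fine), diag = TRUE), arr.ind = TRUE)
  stopifnot(length(scores) == nrow(idx))
  loop_set(tibble::tibble(
    chrom1 = chrom, start1 = (idx[, 1] - 1) * fine,
    end1 = (idx[, 1] - 1) * fine + 1000,
    chrom2 = chrom, start2 = (idx[, 2] - 1) * fine,
    end2 = (idx[, 2] - 1) * fine + 1000,
    score = scores
  ), condition = condition)
}
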