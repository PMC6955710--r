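test_that("absolute thresholding keeps weights at or above the cut", {
  W <- matrix(0, 3, 3); W[1, 2] <- 0.05; W[2, 3] <- 0.2; W[3, 1] <- 0.3
  g <- threshold_absolute(W, 0.2)
  expect_equal(g$W[1, 2], 0)
  expect_equal(g$W[2, 3], 0.2)   # ties at the threshold are kept
  expect_equal(g$W[3, 1], 0.3)
  expect_equal(g$A, (g$W != 0) * 1L)
  g0 <- threshold_absolute(W, 0)
  expect_equal(g0$W, W)          # T = 0 keeps all nonzero entries
})

test_that("proportional thresholding keeps the strongest edges deterministically", {
  set.seed(1)
  W62 <- rand_graph(62, density = 0.9)
  g <- threshold_proportional(W62, 0.10)
  expect_equal(sum(g$A), floor(0.10 * 62 * 61))  # 378 edges
  gall <- threshold_proportional(W62, 1.0)
  expect_equal(gall$W, {W0 <- W62; diag(W0) <- 0; W0})

  # tie at the cut: lower (row, column) kept, runs identical
  W <- matrix(0, 3, 3); W[1, 2] <- 0.5; W[2, 1] <- 0.5; W[3, 1] <- 0.9
  gt <- threshold_proportional(W, 2 / 6)  # keep 2 of 6 possible edges
  expect_equal(gt$W[3, 1], 0.9)
  expect_equal(gt$W[1, 2], 0.5)  # (1,2) beats (2,1) on row order
  expect_equal(gt$W[2, 1], 0)
  expect_identical(gt$W, threshold_proportional(W, 2 / 6)$W)
})

test_that("degrees and strengths match hand counts and conservation laws", {
  # flow edges 2 -> 1 and 3 -> 2 (row = receiver)
  W <- matrix(0, 3, 3); W[1, 2] <- 1; W[2, 3] <- 1
  d <- nodal_degree(threshold_absolute(W, 0))
  expect_equal(d$d_in,  c(1, 1, 0))
  expect_equal(d$d_out, c(0, 1, 1))
  expect_equal(d$d_tot[2], 2)

  expect_equal(nodal_degree(matrix(0, 4, 4))$d_tot, rep(0, 4))

  Ws <- matrix(0, 2, 2); Ws[1, 2] <- 0.4; Ws[2, 1] <- 0.1
  expect_equal(nodal_strength(Ws)[1], 0.5)
  expect_equal(nodal_strength(matrix(0, 3, 3)), rep(0, 3))

  set.seed(2)
  for (k in 1:20) {
    Wr <- rand_graph(sample(3:8, 1))
    d <- nodal_degree(threshold_absolute(Wr, 0))
    expect_equal(sum(d$d_in), sum(d$d_out))
    expect_equal(sum(d$d_in), sum(Wr != 0))
    expect_equal(sum(nodal_strength(Wr)), 2 * sum(Wr))
  }
})

test_that("clustering matches the exhaustive triangle-enumeration oracle", {
  # star graph: no triangles anywhere
  W <- matrix(0, 4, 4); W[2:4, 1] <- 0.5
  expect_equal(clustering_local(W), rep(0, 4))

  # fully connected 3-node graph with equal weights
  W3 <- matrix(0.4, 3, 3); diag(W3) <- 0
  expect_equal(clustering_local(W3), oracle_clustering(W3),
               tolerance = 1e-12)

  set.seed(3)
  for (k in 1:50) {
    Wr <- rand_graph(sample(3:8, 1))
    expect_equal(clustering_local(Wr), oracle_clustering(Wr),
                 tolerance = 1e-10)
  }
  expect_error(clustering_local(matrix(-1, 2, 2)), "nonnegative")
})

test_that("global clustering is the arithmetic mean of local coefficients", {
  expect_equal(clustering_global(c(0.3, 0.3, 0.3)), 0.3)
  expect_equal(clustering_global(c(0, 1)), 0.5)
  set.seed(4)
  Wr <- rand_graph(6)
  expect_equal(clustering_global(Wr), mean(oracle_clustering(Wr)),
               tolerance = 1e-10)
})

test_that("path length uses reciprocal-weight costs over finite pairs", {
  # two nodes, both directions at weight 0.5 -> each L = 2
  W <- matrix(0, 2, 2); W[1, 2] <- 0.5; W[2, 1] <- 0.5
  pl <- path_length(W)
  expect_equal(pl$PL, 2)
  expect_equal(pl$unreachable_frac, 0)

  # flow chain 1 -> 2 -> 3 with unit weights
  Wc <- matrix(0, 3, 3); Wc[2, 1] <- 1; Wc[3, 2] <- 1
  plc <- path_length(Wc)
  expect_equal(plc$L[1, 3], 2)
  expect_equal(plc$PL, 4 / 3)
  expect_equal(plc$unreachable_frac, 0.5)

  expect_error(path_length(matrix(0, 3, 3)), "disconnected")

  set.seed(5)
  for (k in 1:50) {
    Wr <- rand_graph(sample(3:8, 1))
    if (all(Wr == 0)) next
    res <- path_length(Wr)
    orc <- oracle_path_length(Wr)
    expect_equal(res$PL, orc$PL, tolerance = 1e-10)
    expect_equal(res$unreachable_frac, orc$unreachable_frac)
    expect_equal(res$L, oracle_path_costs(Wr), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("sparsity integration is the trapezoid rule on the study grid", {
  grid <- seq(0.10, 0.30, by = 0.05)
  expect_length(grid, 5L)
  expect_equal(sparsity_integral(grid, rep(3, 5)), 0.2 * 3)
  expect_equal(sparsity_integral(grid, 2 * grid + 1),
               0.2 * (2 * 0.2 + 1))   # trapezoid exact for linear
  expect_error(sparsity_integral(0.1, 5), "length")
})

test_that("normalised degree spans 0 to 1", {
  expect_equal(normalized_degree(0, 62), 0)
  expect_equal(normalized_degree(2 * 61, 62), 1)
  expect_equal(normalized_degree(61, 62), 0.5)
})

test_that("raising the absolute threshold never increases degree or strength", {
  set.seed(6)
  for (k in 1:10) {
    Wr <- rand_graph(8)
    prev_d <- Inf; prev_s <- Inf
    for (T in c(0, 0.1, 0.15, 0.2, 0.25, 0.3)) {
      g <- threshold_absolute(Wr, T)
      d <- sum(nodal_degree(g)$d_tot); s <- sum(nodal_strength(g))
      expect_lte(d, prev_d); expect_lte(s, prev_s + 1e-12)
      prev_d <- d; prev_s <- s
    }
  }
})

test_that("metrics scale correctly under uniform weight scaling", {
  set.seed(7)
  W <- rand_graph(7); c0 <- 0.5
  Ws <- c0 * W
  expect_equal(nodal_degree(threshold_absolute(Ws, 0))$d_tot,
               nodal_degree(threshold_absolute(W, 0))$d_tot)
  expect_equal(nodal_strength(Ws), c0 * nodal_strength(W))
  expect_equal(clustering_local(Ws), c0 * clustering_local(W),
               tolerance = 1e-12)
  expect_equal(path_length(Ws)$PL, path_length(W)$PL / c0,
               tolerance = 1e-12)
})

test_that("the per-matrix metric report is internally consistent", {
  set.seed(8)
  W <- rand_graph(10, density = 0.6)
  rep_ <- graph_metrics_report(W)
  expect_setequal(unique(rep_$nodal$threshold), c(0, 0.1, 0.15, 0.2, 0.25, 0.3))
  expect_equal(nrow(rep_$global), 5L)
  expect_equal(rep_$integrals[["CC_int"]],
               sparsity_integral(rep_$global$sparsity, rep_$global$CC))
  nd0 <- rep_$nodal[rep_$nodal$threshold == 0, ]
  expect_equal(nd0$norm_degree, nd0$d_tot / (2 * 9))
})
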