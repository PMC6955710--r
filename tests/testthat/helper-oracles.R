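# Brute-force oracles used to validate the graph metrics and fixtures for
# property-style tests. Everything here is loop-based and independent of the
# package's matrix-algebra implementations.

oracle_degree <- function(W) {
  m <- nrow(W)
  d_in <- d_out <- integer(m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j && W[i, j] != 0) { d_in[i] <- d_in[i] + 1L
                                  d_out[j] <- d_out[j] + 1L }
  }
  data.frame(node = seq_len(m), d_in = d_in, d_out = d_out,
             d_tot = d_in + d_out)
}

oracle_strength <- function(W) {
  m <- nrow(W)
  ns <- numeric(m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) ns[i] <- ns[i] + W[i, j] + W[j, i]
  }
  ns
}

# exhaustive enumeration of all ordered triangle configurations through each
# node: for every ordered pair (j, h) of distinct neighbours, the 8 directed
# triangle variants contribute the geometric mean of their edge weights
oracle_clustering <- function(W) {
  m <- nrow(W)
  C <- numeric(m)
  deg <- oracle_degree(W)
  for (i in seq_len(m)) {
    acc <- 0
    for (j in seq_len(m)) for (h in seq_len(m)) {
      if (j == i || h == i || h == j) next
      for (a in c(W[i, j], W[j, i])) for (b in c(W[i, h], W[h, i]))
        for (cc in c(W[j, h], W[h, j]))
          acc <- acc + (a * b * cc)^(1 / 3)
    }
    dbi <- 0
    for (j in seq_len(m))
      if (j != i && W[i, j] != 0 && W[j, i] != 0) dbi <- dbi + 1
    den <- 2 * (deg$d_tot[i] * (deg$d_tot[i] - 1) - 2 * dbi)
    C[i] <- if (den > 0) acc / den else 0
  }
  C
}

# Floyd-Warshall all-pairs shortest directed path costs in the flow
# orientation (edge j -> i has cost 1 / W[i, j])
oracle_path_costs <- function(W) {
  m <- nrow(W)
  D <- matrix(Inf, m, m); diag(D) <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i != j && W[i, j] > 0) D[j, i] <- min(D[j, i], 1 / W[i, j])
  for (k in seq_len(m)) for (u in seq_len(m)) for (v in seq_len(m))
    if (D[u, k] + D[k, v] < D[u, v]) D[u, v] <- D[u, k] + D[k, v]
  D
}

oracle_path_length <- function(W) {
  D <- oracle_path_costs(W)
  off <- D[row(D) != col(D)]
  list(PL = mean(off[is.finite(off)]), unreachable_frac = mean(!is.finite(off)))
}

# random weighted directed graph with zero diagonal, weights in [0, 1]
rand_graph <- function(m, density = 0.4) {
  W <- matrix(runif(m * m), m, m) * (matrix(runif(m * m), m, m) < density)
  diag(W) <- 0
  W
}

# random stable MVAR model (companion spectral radius <= 0.9)
rand_stable_model <- function(m, p) {
  coeffs <- array(rnorm(p * m * m, sd = 0.4 / sqrt(p * m)), c(p, m, m))
  rad <- companion_radius(coeffs)
  if (rad > 0.9) coeffs <- coeffs * (0.9 / rad)^(seq_len(p) * 0 + 1)  # uniform
  while (companion_radius(coeffs) > 0.9) coeffs <- coeffs * 0.95
  M <- matrix(rnorm(m * m), m)
  var_model(coeffs, noise_cov = crossprod(M) / m + diag(0.5, m))
}
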