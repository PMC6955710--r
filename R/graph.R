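#' Threshold a connectivity matrix at an absolute value
#'
#' Sets every weight strictly below `T` to zero (weights equal to `T` are
#' kept); `T = 0` keeps all nonzero entries.
#'
#' @param W connectivity matrix (m x m, entry `[i, j]` = flow j -> i) or a
#'   `connectivity_matrix`.
#' @param T absolute threshold (>= 0); the study grid is
#'   `c(0, 0.1, 0.15, 0.2, 0.25, 0.3)` with 0.2 the usual display value.
#' @return object of class `thresholded_graph`: list with `W` (zeros = absent
#'   edges, zero diagonal), binary adjacency `A` (`A[i,j] = 1` iff
#'   `W[i,j] != 0`), and `scheme` describing the thresholding.
#' @export
threshold_absolute <- function(W, T = 0.2) {
  stopifnot(T >= 0)
  W <- as_weight_matrix(W)
  W[W < T] <- 0
  diag(W) <- 0
  thresholded_graph(W, scheme = list(type = "absolute", value = T))
}

#' Threshold a connectivity matrix at a proportional sparsity
#'
#' Keeps the `floor(sparsity * m * (m - 1))` largest off-diagonal weights.
#' Ties at the cut are broken deterministically by (row, column) index order
#' (lower indices kept first).
#'
#' @inheritParams threshold_absolute
#' @param sparsity fraction of possible directed edges to keep, in (0, 1];
#'   the study range is 0.10 to 0.30 in steps of 0.05.
#' @return a `thresholded_graph`.
#' @export
threshold_proportional <- function(W, sparsity = 0.2) {
  stopifnot(sparsity > 0, sparsity <= 1)
  W <- as_weight_matrix(W)
  diag(W) <- 0
  m <- nrow(W)
  k <- floor(sparsity * m * (m - 1))
  off <- which(row(W) != col(W))
  ord <- off[order(-W[off], row(W)[off], col(W)[off])]
  keep <- ord[seq_len(min(k, length(ord)))]
  W2 <- matrix(0, m, m, dimnames = dimnames(W))
  W2[keep] <- W[keep]
  thresholded_graph(W2, scheme = list(type = "proportional",
                                      value = sparsity))
}

as_weight_matrix <- function(W) {
  if (inherits(W, "connectivity_matrix")) W <- W$W
  if (inherits(W, "thresholded_graph")) W <- W$W
  W <- as.matrix(W)
  if (any(W < 0)) stop("weights must be nonnegative")
  W
}

thresholded_graph <- function(W, scheme) {
  A <- (W != 0) * 1L
  structure(list(W = W, A = A, scheme = scheme),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("<thresholded_graph> %d nodes, %d directed edges (%s %.3g)\n",
              nrow(x$W), sum(x$A), x$scheme$type, x$scheme$value))
  invisible(x)
}

#' Nodal in-, out- and total degree
#'
#' With the row = receiver convention, `d_in(i)` counts nonzero entries in
#' row `i` and `d_out(i)` nonzero entries in column `i`;
#' `d_tot = d_in + d_out`.
#'
#' @param g a `thresholded_graph` (or nonnegative weight matrix with zero
#'   diagonal).
#' @return data frame with columns `node`, `d_in`, `d_out`, `d_tot`.
#' @export
nodal_degree <- function(g) {
  A <- if (inherits(g, "thresholded_graph")) g$A else (as_weight_matrix(g) != 0) * 1L
  diag(A) <- 0L
  data.frame(node = seq_len(nrow(A)), d_in = rowSums(A), d_out = colSums(A),
             d_tot = rowSums(A) + colSums(A))
}

#' Nodal strength
#'
#' Sum of all incoming and outgoing edge weights per node:
#' `NS(i) = sum_j W[i, j] + sum_j W[j, i]`.
#'
#' @param W nonnegative weight matrix (zero diagonal) or `thresholded_graph`.
#' @return numeric vector of per-node strengths.
#' @export
nodal_strength <- function(W) {
  W <- as_weight_matrix(W)
  diag(W) <- 0
  rowSums(W) + colSums(W)
}

#' Weighted directed local clustering coefficient
#'
#' Fagiolo's weighted directed clustering: with `S = W^(1/3) + (W')^(1/3)`
#' (entrywise cube roots) and `A` the binary adjacency,
#' `C_i = [S^3]_ii / (2 * (d_tot(i) * (d_tot(i) - 1) - 2 * d_bi(i)))`,
#' where `d_bi(i) = [A^2]_ii` counts reciprocal neighbour pairs. `C_i = 0`
#' when the denominator is zero. For weights in \[0, 1\] this keeps
#' `C_i` in \[0, 1\]; the numerator sums geometric means of the weights of all
#' existing directed triangles through node `i`.
#'
#' @param W nonnegative weight matrix with weights in \[0, 1\] (zero diagonal)
#'   or a `thresholded_graph`.
#' @return numeric vector of per-node clustering coefficients.
#' @export
clustering_local <- function(W) {
  W <- as_weight_matrix(W)
  diag(W) <- 0
  A <- (W != 0) * 1
  S <- W^(1/3) + t(W)^(1/3)
  num <- diag(S %*% S %*% S)
  dtot <- rowSums(A) + colSums(A)
  dbi <- diag(A %*% A)
  den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
  ifelse(den > 0, num / den, 0)
}

#' Global clustering coefficient
#'
#' Arithmetic mean of the local clustering coefficients.
#'
#' @param c_i numeric vector of local coefficients (or a weight matrix, in
#'   which case [clustering_local()] is applied first).
#' @return scalar CC.
#' @export
clustering_global <- function(c_i) {
  if (is.matrix(c_i) || inherits(c_i, c("thresholded_graph",
                                        "connectivity_matrix")))
    c_i <- clustering_local(c_i)
  if (length(c_i) == 0) stop("empty clustering vector")
  mean(c_i)
}

#' Characteristic path length
#'
#' Edge lengths are the reciprocals of the edge weights; `L_ij` is the cost
#' of the shortest directed path from `i` to `j` along the flow direction,
#' and PL is the mean of the finite `L_ij` over ordered pairs `i != j`. The
#' fraction of unreachable (infinite) pairs is reported alongside, since
#' thresholding can disconnect the graph.
#'
#' @param W nonnegative weight matrix (entry `[i, j]` = flow j -> i) or a
#'   `thresholded_graph`.
#' @return list with `PL` (mean finite shortest-path cost),
#'   `unreachable_frac`, and `L` (the full cost matrix, `L[u, v]` = cost from
#'   `u` to `v` in the flow direction).
#' @export
path_length <- function(W) {
  W <- as_weight_matrix(W)
  diag(W) <- 0
  m <- nrow(W)
  # flow graph: edge j -> i for W[i, j] > 0, so adjacency = t(W)
  g <- igraph::graph_from_adjacency_matrix(t(W), mode = "directed",
                                           weighted = TRUE)
  L <- igraph::distances(g, mode = "out",
                         weights = 1 / igraph::E(g)$weight)
  off <- L[row(L) != col(L)]
  fin <- is.finite(off)
  if (!any(fin)) stop("disconnected graph: no finite directed path costs")
  list(PL = mean(off[fin]), unreachable_frac = mean(!fin), L = L)
}

#' Trapezoidal integral of a metric over a sparsity grid
#'
#' @param sparsities sorted grid of sparsity levels (>= 2 points); the study
#'   grid is `seq(0.10, 0.30, by = 0.05)`.
#' @param values metric values at those levels.
#' @return the trapezoidal integral.
#' @export
sparsity_integral <- function(sparsities, values) {
  stopifnot(length(sparsities) >= 2, length(values) == length(sparsities),
            !is.unsorted(sparsities))
  pracma::trapz(sparsities, values)
}

#' Normalised total nodal degree
#'
#' `d_tot / (2 * (m - 1))`: 0 for an isolated node, 1 for a node connected
#' to and from every other node.
#'
#' @param d_tot total degree (vector or scalar).
#' @param m number of nodes (>= 2).
#' @return fraction in \[0, 1\].
#' @export
normalized_degree <- function(d_tot, m) {
  stopifnot(m >= 2)
  d_tot / (2 * (m - 1))
}

#' Graph-metric report for one connectivity matrix
#'
#' Computes, for each absolute threshold: per-node degree (raw and
#' normalised) and strength; and for each sparsity level: global clustering
#' coefficient and characteristic path length, plus their trapezoidal
#' integrals over the sparsity range.
#'
#' @param W a `connectivity_matrix` or weight matrix.
#' @param thresholds absolute threshold grid.
#' @param sparsities proportional sparsity grid.
#' @return list with `nodal` (data frame: threshold, node, d_in, d_out,
#'   d_tot, norm_degree, strength), `global` (data frame: sparsity, CC, PL,
#'   unreachable_frac), and `integrals` (named vector `CC_int`, `PL_int`).
#' @export
graph_metrics_report <- function(W,
                                 thresholds = c(0, 0.1, 0.15, 0.2, 0.25, 0.3),
                                 sparsities = seq(0.10, 0.30, by = 0.05)) {
  Wm <- as_weight_matrix(W)
  m <- nrow(Wm)
  nodal <- do.call(rbind, lapply(thresholds, function(T) {
    g <- threshold_absolute(Wm, T)
    d <- nodal_degree(g)
    d$norm_degree <- normalized_degree(d$d_tot, m)
    d$strength <- nodal_strength(g)
    cbind(threshold = T, d)
  }))
  glob <- do.call(rbind, lapply(sparsities, function(s) {
    g <- threshold_proportional(Wm, s)
    pl <- path_length(g)
    data.frame(sparsity = s, CC = clustering_global(clustering_local(g)),
               PL = pl$PL, unreachable_frac = pl$unreachable_frac)
  }))
  list(nodal = nodal, global = glob,
       integrals = c(CC_int = sparsity_integral(glob$sparsity, glob$CC),
                     PL_int = sparsity_integral(glob$sparsity, glob$PL)))
}
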