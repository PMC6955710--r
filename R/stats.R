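#' Pairwise t-test between two sets of per-subject values
#'
#' Paired t for within-group time-on-task contrasts (same participants at two
#' levels), Welch two-sample t for between-group contrasts (different
#' participants). Degenerate cases are flagged rather than erroring: a paired
#' contrast with identical values gives `t = 0, p = 1`; a constant nonzero
#' shift with zero noise gives `t = +/-Inf, p = 0` with `degenerate = TRUE`.
#'
#' @param a,b numeric vectors of per-subject values.
#' @param paired logical; paired requires equal lengths.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
pairwise_ttest <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (paired && length(a) != length(b))
    stop("paired test requires equal group sizes")
  if (paired) {
    d <- a - b
    if (sd(d) == 0) {
      if (mean(d) == 0) return(list(t = 0, p = 1, df = length(d) - 1,
                                    degenerate = TRUE))
      return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
                  degenerate = TRUE))
    }
    tt <- t.test(a, b, paired = TRUE)
  } else {
    if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) return(list(t = 0, p = 1,
                                          df = length(a) + length(b) - 2,
                                          degenerate = TRUE))
      return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                  df = length(a) + length(b) - 2, degenerate = TRUE))
    }
    tt <- t.test(a, b, paired = FALSE, var.equal = FALSE)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Bonferroni-Holm step-down correction
#'
#' Sorts the p-values ascending and rejects while
#' `p_(k) <= alpha / (m - k + 1)`; adjusted p-values use the standard
#' monotone max construction (as in `stats::p.adjust(method = "holm")`).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param alpha family-wise error level (default 0.05).
#' @return list with `adjusted` (Holm-adjusted p-values, original order) and
#'   `reject` (logical decisions at `alpha`).
#' @export
holm_correct <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adj <- p.adjust(p_values, method = "holm")
  list(adjusted = adj, reject = adj <= alpha)
}

#' Per-electrode t-map between two groups
#'
#' Computes one t-statistic per electrode from subject x electrode metric
#' matrices, and masks electrodes whose |t| reaches the significance
#' criterion (default 2.5).
#'
#' @param metric_a,metric_b numeric matrices, subjects x electrodes, with
#'   identical electrode columns.
#' @param paired logical; see [pairwise_ttest()].
#' @param t_threshold mask criterion on |t| (default 2.5).
#' @return data frame keyed by electrode with columns `electrode`, `t`, `p`,
#'   `significant`.
#' @export
electrode_tmap <- function(metric_a, metric_b, paired = FALSE,
                           t_threshold = 2.5) {
  metric_a <- as.matrix(metric_a); metric_b <- as.matrix(metric_b)
  ea <- colnames(metric_a); eb <- colnames(metric_b)
  if (ncol(metric_a) != ncol(metric_b) ||
      (!is.null(ea) && !is.null(eb) && !identical(ea, eb)))
    stop("labelling error: electrode sets differ between groups")
  el <- ea %||% paste0("e", seq_len(ncol(metric_a)))
  res <- lapply(seq_len(ncol(metric_a)), function(j)
    pairwise_ttest(metric_a[, j], metric_b[, j], paired = paired))
  tv <- vapply(res, `[[`, numeric(1), "t")
  pv <- vapply(res, `[[`, numeric(1), "p")
  data.frame(electrode = el, t = tv, p = pv,
             significant = abs(tv) >= t_threshold)
}

#' One-vs-all weighted degree differences
#'
#' For each enhancement-group subject `e`, the weighted difference from the
#' vigilance reference group:
#' `Delta(e) = sum_v weight_v * (value_e - value_v)`; with uniform weights
#' this is `value_e - mean(vigilance values)`. Positive values indicate
#' enhancement above the vigilance reference. The same construction applies
#' to reaction-time changes.
#'
#' @param enh_values per-subject values in the enhancement group.
#' @param vig_values per-subject values in the vigilance (reference) group.
#' @param weights reference weights summing to 1; default uniform.
#' @return numeric vector of per-enhancement-subject deltas.
#' @export
delta_one_vs_all <- function(enh_values, vig_values, weights = NULL) {
  stopifnot(length(enh_values) > 0, length(vig_values) > 0)
  if (is.null(weights)) weights <- rep(1 / length(vig_values),
                                       length(vig_values))
  if (length(weights) != length(vig_values) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("config error: weights must match the reference group and sum to 1")
  enh_values - sum(weights * vig_values)
}

#' Pearson correlation between degree change and reaction-time change
#'
#' @param delta_degree,delta_rt numeric vectors (n >= 3, finite).
#' @return list with `r`, `p` (two-sided), `n`.
#' @export
correlate_delta <- function(delta_degree, delta_rt) {
  stopifnot(length(delta_degree) == length(delta_rt),
            length(delta_degree) >= 3)
  if (!all(is.finite(delta_degree)) || !all(is.finite(delta_rt)))
    stop("non-finite values in correlation input")
  if (sd(delta_degree) == 0 || sd(delta_rt) == 0)
    stop("degenerate correlation: zero variance")
  ct <- cor.test(delta_degree, delta_rt, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(delta_degree))
}
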