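#' Fit an MVAR model to one epoch by least squares
#'
#' Estimates the lag coefficient matrices `A(1..p)` of a multivariate
#' autoregressive model `x(t) = sum_r A(r) x(t-r) + e(t)` by (optionally
#' ridge-regularised) least squares, together with the residual covariance.
#'
#' The ridge penalty is scale-free: the effective penalty added to the
#' regressor Gram matrix is `ridge * mean(diag(Gram))`, so the same `ridge`
#' value behaves identically for signals in microvolts or volts. A small
#' ridge (e.g. `1e-6`) is required for common-average-referenced data, whose
#' channel sums are exactly zero and whose regressor matrix is therefore
#' rank-deficient.
#'
#' @param epoch numeric matrix, channels x samples.
#' @param p model order (number of lags); default 7.
#' @param ridge nonnegative relative ridge penalty; default 0.
#' @return a `var_model` with estimated `coeffs` (p x m x m), residual
#'   covariance `noise_cov` (maximum-likelihood scaling), `order`, and the
#'   effective residual sample count `n_eff`.
#' @export
fit_mvar <- function(epoch, p = 7L, ridge = 0) {
  epoch <- as.matrix(epoch)
  m <- nrow(epoch); n <- ncol(epoch)
  stopifnot(p >= 1, ridge >= 0)
  if (n <= m * p)
    stop("too few samples (", n, ") for m*p = ", m * p, " regressors")
  Y <- epoch[, (p + 1):n, drop = FALSE]
  X <- do.call(rbind, lapply(seq_len(p), function(r)
    epoch[, (p + 1 - r):(n - r), drop = FALSE]))
  G <- X %*% t(X)
  if (ridge > 0) G <- G + ridge * mean(diag(G)) * diag(m * p)
  if (rcond(G) < 1e-14)
    stop("rank-deficient regressor matrix; re-fit with ridge > 0 ",
         "(e.g. ridge = 1e-6)")
  B <- Y %*% t(X) %*% solve(G)
  n_eff <- n - p
  R <- Y - B %*% X
  coeffs <- array(0, c(p, m, m))
  for (r in seq_len(p)) coeffs[r, , ] <- B[, ((r - 1) * m + 1):(r * m)]
  S <- (R %*% t(R)) / n_eff                # MLE residual covariance
  S <- (S + t(S)) / 2
  # built directly: fitted residual covariances may be singular (e.g. after
  # common-average referencing), which var_model()'s SPD contract rejects
  structure(list(coeffs = coeffs, noise_cov = S, order = p, n_eff = n_eff),
            class = "var_model")
}

#' Select the MVAR model order by AIC
#'
#' Fits orders `1..p_max` and returns the minimiser of
#' `AIC(p) = log det(Sigma_p) + 2 p m^2 / N_eff`, where `Sigma_p` is the
#' maximum-likelihood residual covariance and `N_eff` the residual sample
#' count. The full AIC curve is returned for audit.
#'
#' @inheritParams fit_mvar
#' @param p_max largest order considered.
#' @return list with `order` (the argmin), `aic` (numeric vector over
#'   `1..p_max`).
#' @export
select_order_aic <- function(epoch, p_max = 10L, ridge = 0) {
  epoch <- as.matrix(epoch)
  m <- nrow(epoch); n <- ncol(epoch)
  if (p_max * m >= n / 2)
    stop("p_max too large for the epoch length (need p_max * m < samples/2)")
  aic <- vapply(seq_len(p_max), function(p) {
    fit <- fit_mvar(epoch, p, ridge)
    ld <- determinant(fit$noise_cov, logarithm = TRUE)
    if (ld$sign <= 0)
      stop("residual covariance not positive definite at order ", p)
    as.numeric(ld$modulus) + 2 * p * m^2 / fit$n_eff
  }, numeric(1))
  list(order = which.min(aic), aic = aic)
}

#' Partial directed coherence spectrum of an MVAR model
#'
#' Computes `Abar(f) = I - sum_r A(r) exp(-i 2 pi f r / fs)` and the PDC
#' magnitude `|PDC_ij(f)| = |Abar_ij(f)| / sqrt(abar_j(f)^H abar_j(f))`, i.e.
#' the column-normalised directed influence of channel `j` on channel `i` at
#' frequency `f`. By construction `sum_i |PDC_ij(f)|^2 = 1` for every sender
#' column `j` and every frequency, and all entries lie in \[0, 1\].
#'
#' @param model a `var_model`.
#' @param freqs frequency grid in Hz, inside (0, fs/2); default
#'   `seq(0.5, 30, by = 0.5)`.
#' @param fs sampling rate in Hz.
#' @return object of class `pdc_spectrum`: list with `values` (freqs x m x m
#'   array of PDC magnitudes, entry `[f, i, j]` = flow j -> i) and `freqs`.
#' @export
pdc_spectrum <- function(model, freqs = seq(0.5, 30, by = 0.5), fs = 500) {
  stopifnot(inherits(model, "var_model"))
  if (any(freqs <= 0 | freqs >= fs / 2))
    stop("freqs must lie strictly inside (0, fs/2)")
  p <- model$order
  m <- dim(model$coeffs)[2]
  A <- lapply(seq_len(p), function(r) model$coeffs[r, , ])
  vals <- array(0, c(length(freqs), m, m))
  for (k in seq_along(freqs)) {
    Af <- diag(m) + 0i
    for (r in seq_len(p))
      Af <- Af - A[[r]] * exp(-2i * pi * freqs[k] * r / fs)
    cn <- sqrt(colSums(Mod(Af)^2))
    if (any(cn == 0)) stop("degenerate transfer matrix: zero column norm")
    vals[k, , ] <- Mod(Af) / matrix(cn, m, m, byrow = TRUE)
  }
  structure(list(values = vals, freqs = freqs), class = "pdc_spectrum")
}

#' Band-average a PDC spectrum into a connectivity matrix
#'
#' Arithmetic mean of the PDC magnitudes over the frequency bins falling in
#' `\[lo, hi\]` (defaults 0.5-30 Hz, the broad band used for the weighted
#' directed adjacency matrices).
#'
#' @param spec a `pdc_spectrum`.
#' @param lo,hi band edges in Hz.
#' @return object of class `connectivity_matrix`: list with `W` (m x m,
#'   entry `[i, j]` = band-averaged flow j -> i), `band`, `n_epochs_averaged`
#'   (1), `threshold_applied` (`NA`), `channel_labels` (`NULL`).
#' @export
band_average <- function(spec, lo = 0.5, hi = 30) {
  stopifnot(inherits(spec, "pdc_spectrum"))
  sel <- spec$freqs >= lo & spec$freqs <= hi
  if (!any(sel)) stop("config error: empty band [", lo, ", ", hi, "] Hz")
  W <- apply(spec$values[sel, , , drop = FALSE], c(2, 3), mean)
  connectivity_matrix(W, band = c(lo, hi), n_epochs_averaged = 1L)
}

#' Connectivity-matrix container
#'
#' @param W m x m nonnegative matrix; entry `[i, j]` is the flow from channel
#'   `j` to channel `i` (row = receiver, column = sender).
#' @param band frequency band `(lo, hi)` in Hz the weights were averaged over.
#' @param n_epochs_averaged number of epochs averaged into `W`.
#' @param channel_labels optional channel names (row/col names of `W`).
#' @param threshold_applied threshold provenance (`NA` if unthresholded).
#' @return an object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(W, band = c(0.5, 30),
                                n_epochs_averaged = 1L,
                                channel_labels = NULL,
                                threshold_applied = NA) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == ncol(W), all(W >= 0))
  if (!is.null(channel_labels)) dimnames(W) <- list(channel_labels,
                                                    channel_labels)
  structure(list(W = W, band = band,
                 n_epochs_averaged = as.integer(n_epochs_averaged),
                 channel_labels = channel_labels %||% rownames(W),
                 threshold_applied = threshold_applied),
            class = "connectivity_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d (row=receiver, column=sender), band %g-%g Hz, %d epoch(s)\n",
              nrow(x$W), ncol(x$W), x$band[1], x$band[2],
              x$n_epochs_averaged))
  invisible(x)
}

#' Per-block PDC connectivity from an epoch set
#'
#' For every kept epoch in the requested time-on-task block: fit an MVAR
#' model, compute its PDC spectrum, band-average it; then average the
#' per-epoch matrices entrywise and zero the diagonal for graph use.
#'
#' @param epochs an `epoch_set`.
#' @param block block level (1, 2 or 3).
#' @param p MVAR order (default 7) or `"aic"` to select the order on the
#'   first kept epoch via [select_order_aic()].
#' @param ridge relative ridge penalty passed to [fit_mvar()].
#' @param freqs frequency grid (Hz).
#' @param band band `(lo, hi)` averaged into the weights.
#' @param p_max order search bound when `p = "aic"`.
#' @return a `connectivity_matrix` with zero diagonal.
#' @export
block_connectivity <- function(epochs, block, p = 7L, ridge = 0,
                               freqs = seq(0.5, 30, by = 0.5),
                               band = c(0.5, 30), p_max = 10L) {
  sel <- which(epochs$kept_mask & epochs$block_labels == block)
  if (length(sel) == 0) stop("no kept epochs in block ", block)
  if (identical(p, "aic"))
    p <- select_order_aic(epochs$data[sel[1], , ], p_max, ridge)$order
  acc <- NULL
  for (k in sel) {
    fit <- fit_mvar(epochs$data[k, , ], p, ridge)
    Wk <- band_average(pdc_spectrum(fit, freqs, epochs$fs),
                       band[1], band[2])$W
    acc <- if (is.null(acc)) Wk else acc + Wk
  }
  W <- acc / length(sel)
  diag(W) <- 0
  connectivity_matrix(W, band = band, n_epochs_averaged = length(sel),
                      channel_labels = epochs$channel_labels)
}
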