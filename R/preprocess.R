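#' Zero-phase FIR band-pass filter
#'
#' Designs a linear-phase (Hamming-window) FIR band-pass filter and applies it
#' forward and backward (zero phase, so epoch timing is not distorted) to each
#' channel via FFT convolution.
#'
#' @param recording a `session_recording` (or any list with `signal` channels
#'   x samples and `fs`).
#' @param lo,hi pass-band edges in Hz; defaults 0.1 and 30.
#' @param n_taps filter length (odd); default `min(8449, ...)` bounded so the
#'   filter is shorter than a third of the signal. Long filters are needed for
#'   the 0.1 Hz cut-off.
#' @return the recording with filtered `signal`.
#' @export
bandpass_fir <- function(recording, lo = 0.1, hi = 30, n_taps = NULL) {
  fs <- recording$fs
  if (!(0 < lo && lo < hi)) stop("config error: need 0 < lo < hi")
  if (hi >= fs / 2) stop("config error: hi must be below the Nyquist rate")
  n <- ncol(recording$signal)
  if (is.null(n_taps)) n_taps <- min(8449L, 2L * floor(n / 6) + 1L)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1L
  if (n_taps < 9) stop("config error: signal too short to filter")
  h <- design_fir_bandpass(lo, hi, fs, n_taps)
  recording$signal <- t(apply(recording$signal, 1, filtfilt_fir, h = h))
  recording
}

#' Design a linear-phase FIR band-pass filter
#'
#' @inheritParams bandpass_fir
#' @param fs sampling rate (Hz).
#' @return numeric vector of `n_taps` filter coefficients (symmetric).
#' @export
design_fir_bandpass <- function(lo, hi, fs, n_taps = 1001L) {
  as.numeric(signal::fir1(n_taps - 1L, c(lo, hi) / (fs / 2), type = "pass"))
}

# forward-backward application of a symmetric FIR via FFT convolution,
# keeping the centre-aligned ("same") segment each pass
filtfilt_fir <- function(x, h) {
  n <- length(x); L <- length(h); half <- (L - 1) / 2
  one_pass <- function(v) {
    y <- convolve(c(v, numeric(L)), rev(h), type = "open")
    y[(half + 1):(half + n)]
  }
  rev(one_pass(rev(one_pass(x))))
}

#' Re-reference to the common average
#'
#' Subtracts the per-sample mean over channels from every channel.
#'
#' @param recording a recording with `signal` (channels x samples).
#' @return the recording, re-referenced.
#' @export
rereference_car <- function(recording) {
  if (nrow(recording$signal) < 2) stop("need at least 2 channels for CAR")
  recording$signal <- sweep(recording$signal, 2, colMeans(recording$signal))
  recording
}

#' Segment a recording into baseline-corrected epochs
#'
#' Cuts one fixed-length epoch per event (starting at the event sample),
#' subtracts the per-epoch per-channel mean (baseline / DC removal), and
#' assigns each epoch to a time-on-task block from the recording's
#' `block_bounds` (default: three equal thirds of the recording, i.e. the
#' 0-20, 21-40 and 41-60 minute levels of a 60-minute session).
#'
#' @param recording a recording with `signal`, `fs` and optionally
#'   `block_bounds`.
#' @param events target-onset sample indices (1-based); default
#'   `recording$events`.
#' @param epoch_ms epoch length in milliseconds (default 1200, i.e. 600
#'   samples at 500 Hz).
#' @return an object of class `epoch_set`: list with `data` (epochs x
#'   channels x samples array), `fs`, `epoch_ms`, `block_labels`, `kept_mask`
#'   (all `TRUE`; see [reject_epochs()]), `channel_labels`.
#' @export
epoch_and_baseline <- function(recording, events = recording$events,
                               epoch_ms = 1200) {
  fs <- recording$fs
  L <- round(epoch_ms / 1000 * fs)
  n <- ncol(recording$signal)
  ok <- events >= 1 & (events + L - 1) <= n
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the recording bounds; skipped")
  events <- events[ok]
  if (length(events) == 0) stop("no in-bounds events to epoch")
  bb <- recording$block_bounds
  if (is.null(bb)) {
    third <- floor(n / 3)
    bb <- cbind(c(1, third + 1, 2 * third + 1), c(third, 2 * third, n))
  }
  labels <- vapply(events, function(e) {
    b <- which(e >= bb[, 1] & e <= bb[, 2])
    if (length(b) == 0) NA_integer_ else as.integer(b[1])
  }, integer(1))
  m <- nrow(recording$signal)
  dat <- array(0, c(length(events), m, L))
  for (k in seq_along(events)) {
    ep <- recording$signal[, events[k]:(events[k] + L - 1), drop = FALSE]
    dat[k, , ] <- ep - rowMeans(ep)
  }
  structure(list(data = dat, fs = fs, epoch_ms = epoch_ms,
                 block_labels = labels,
                 kept_mask = rep(TRUE, length(events)),
                 channel_labels = recording$channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz; %d kept\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              sum(x$kept_mask)))
  invisible(x)
}

#' Reject epochs exceeding an amplitude limit
#'
#' Marks as rejected any epoch in which any channel exceeds `amp_limit`
#' microvolts in absolute value (automated surrogate for manual artifact
#' screening).
#'
#' @param epochs an `epoch_set`.
#' @param amp_limit rejection threshold in microvolts (default 100).
#' @return the `epoch_set` with an updated `kept_mask`.
#' @export
reject_epochs <- function(epochs, amp_limit = 100) {
  stopifnot(amp_limit > 0)
  peak <- apply(abs(epochs$data), 1, max)
  keep <- epochs$kept_mask & (peak <= amp_limit)
  if (!any(keep))
    stop("all epochs rejected at amp_limit = ", amp_limit,
         " (max epoch peak ", signif(min(peak), 4), " uV)")
  epochs$kept_mask <- keep
  epochs
}
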