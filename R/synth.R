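#' Directed coupling specification for synthetic MVAR sessions
#'
#' Defines the ground-truth directed network a synthetic session is generated
#' from: a lag-1 autoregressive self-term per channel plus a set of directed
#' edges, and one multiplier per time-on-task block that scales every edge
#' strength in that block.
#'
#' @param n_channels number of channels (network nodes).
#' @param edges data frame with columns `source`, `target` (channel indices)
#'   and `strength` (coupling coefficient in (0, 1)).
#' @param self_coef per-channel AR(1) self-term in (-1, 1); recycled to
#'   `n_channels`.
#' @param order model order (lag count); coupling is placed at lag 1, higher
#'   lags are zero.
#' @param block_scale numeric vector of per-block multipliers on edge
#'   strengths, one per time-on-task block, or `NULL` to let
#'   [simulate_session()] pick the group default.
#' @return an object of class `coupling_spec`.
#' @seealso [default_coupling_spec()], [make_var_model()], [simulate_session()]
#' @export
coupling_spec <- function(n_channels, edges = NULL, self_coef = 0.25,
                          order = 1L, block_scale = NULL) {
  stopifnot(n_channels >= 1, order >= 1)
  if (is.null(edges)) {
    edges <- data.frame(source = integer(0), target = integer(0),
                        strength = numeric(0))
  }
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    if (!all(is.finite(edges$strength)))
      stop("invalid coupling spec: non-finite edge strengths")
    if (any(edges$source == edges$target))
      stop("invalid coupling spec: self-loops (source == target) not allowed")
    if (any(edges$source < 1 | edges$source > n_channels |
            edges$target < 1 | edges$target > n_channels))
      stop("invalid coupling spec: edge endpoints outside 1..n_channels")
  }
  self_coef <- rep_len(self_coef, n_channels)
  if (!all(is.finite(self_coef)) || any(abs(self_coef) >= 1))
    stop("invalid coupling spec: self_coef must be finite and in (-1, 1)")
  if (!is.null(block_scale) && !all(is.finite(block_scale)))
    stop("invalid coupling spec: non-finite block_scale")
  structure(list(n_channels = as.integer(n_channels), edges = edges,
                 self_coef = self_coef, order = as.integer(order),
                 block_scale = block_scale),
            class = "coupling_spec")
}

#' Default random coupling specification
#'
#' Draws a sparse directed ground-truth network in which every channel
#' receives `n_incoming` edges from distinct random senders, with strengths
#' uniform on `strength_range`. The defaults give a companion spectral radius
#' of about 0.8 at full block scale, i.e. a strongly coupled but comfortably
#' stationary system whose band-averaged PDC values land in the 0.2-0.35
#' range probed by the 0-0.3 threshold grid.
#'
#' @param n_channels number of channels.
#' @param n_incoming incoming edges per channel.
#' @param strength_range range of uniform edge strengths.
#' @param self_coef AR(1) self-term (scalar or per channel).
#' @param seed optional RNG seed for reproducible topologies.
#' @inheritParams coupling_spec
#' @return a `coupling_spec`.
#' @export
default_coupling_spec <- function(n_channels = 62, n_incoming = 2,
                                  strength_range = c(0.18, 0.35),
                                  self_coef = 0.25, block_scale = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  src <- tgt <- integer(0)
  for (i in seq_len(n_channels)) {
    k <- min(n_incoming, n_channels - 1)
    cand <- setdiff(seq_len(n_channels), i)
    src <- c(src, cand[sample.int(length(cand), k)])
    tgt <- c(tgt, rep(i, k))
  }
  edges <- data.frame(source = src, target = tgt,
                      strength = runif(length(src), strength_range[1],
                                       strength_range[2]))
  coupling_spec(n_channels, edges, self_coef = self_coef,
                block_scale = block_scale)
}

#' MVAR model container
#'
#' @param coeffs numeric array of shape `(p, m, m)`; `coeffs[r, i, j]` is the
#'   lag-`r` autoregressive coefficient from channel `j` onto channel `i`
#'   (row = receiver).
#' @param noise_cov `m x m` symmetric positive-definite innovation covariance.
#' @return an object of class `var_model` with elements `coeffs`, `noise_cov`
#'   and `order`.
#' @export
var_model <- function(coeffs, noise_cov = NULL) {
  if (length(dim(coeffs)) != 3 || dim(coeffs)[2] != dim(coeffs)[3])
    stop("coeffs must be a (p, m, m) array")
  m <- dim(coeffs)[2]
  if (is.null(noise_cov)) noise_cov <- diag(m)
  if (!isTRUE(all.equal(noise_cov, t(noise_cov), tolerance = 1e-12)))
    stop("noise_cov must be symmetric")
  if (any(eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("noise_cov must be positive definite")
  structure(list(coeffs = coeffs, noise_cov = noise_cov,
                 order = dim(coeffs)[1]),
            class = "var_model")
}

#' Companion-matrix spectral radius of an MVAR coefficient array
#'
#' @param coeffs `(p, m, m)` coefficient array (or a `var_model`).
#' @return the modulus of the largest companion-matrix eigenvalue; the model
#'   is stationary iff this is `< 1`.
#' @export
companion_radius <- function(coeffs) {
  if (inherits(coeffs, "var_model")) coeffs <- coeffs$coeffs
  p <- dim(coeffs)[1]; m <- dim(coeffs)[2]
  comp <- matrix(0, m * p, m * p)
  for (r in seq_len(p)) comp[1:m, ((r - 1) * m + 1):(r * m)] <- coeffs[r, , ]
  if (p > 1) comp[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Is an MVAR model stable (stationary)?
#' @param model a `var_model`.
#' @return logical.
#' @export
is_stable <- function(model) companion_radius(model) < 1

#' Build a ground-truth MVAR model for one time-on-task block
#'
#' Places each channel's self-term on the lag-1 diagonal and, for every edge
#' `(source -> target, strength)`, the value `block_scale[block] * strength`
#' at lag-1 position `(target, source)`. If the resulting model is unstable,
#' all coefficients are shrunk uniformly until the companion spectral radius
#' is at most 0.95 (graph topology preserved).
#'
#' @param spec a [coupling_spec()].
#' @param block block index (1-based); must not exceed
#'   `length(spec$block_scale)`.
#' @param noise_sd innovation standard deviation, identical across channels
#'   (microvolts); innovations are uncorrelated Gaussian.
#' @return a stable `var_model`.
#' @export
make_var_model <- function(spec, block = 1L, noise_sd = 10) {
  stopifnot(inherits(spec, "coupling_spec"))
  scales <- spec$block_scale
  if (is.null(scales)) scales <- 1
  if (block < 1 || block > length(scales))
    stop("block index outside the spec's block_scale")
  m <- spec$n_channels
  A1 <- diag(spec$self_coef, m)
  if (nrow(spec$edges) > 0) {
    s <- spec$edges$strength * scales[block]
    if (!all(is.finite(s))) stop("invalid coupling spec: non-finite strengths")
    A1[cbind(spec$edges$target, spec$edges$source)] <- s
  }
  coeffs <- array(0, c(spec$order, m, m))
  coeffs[1, , ] <- A1
  rad <- companion_radius(coeffs)
  while (rad > 0.95) {          # uniform shrinkage, topology unchanged
    coeffs <- coeffs * (0.95 / rad)
    rad <- companion_radius(coeffs)
  }
  var_model(coeffs, noise_cov = diag(noise_sd^2, m))
}

#' Simulate a stationary MVAR process
#'
#' @param model a stable `var_model`.
#' @param n_samples number of samples to return (after burn-in).
#' @param burn_in samples discarded at the start so the process reaches its
#'   stationary distribution.
#' @param seed optional RNG seed; identical seeds give identical output.
#' @return `m x n_samples` numeric matrix (channels x samples).
#' @export
simulate_var <- function(model, n_samples, burn_in = 500L, seed = NULL) {
  stopifnot(inherits(model, "var_model"), n_samples > model$order)
  if (!is_stable(model)) stop("unstable MVAR model: spectral radius >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- model$order
  m <- dim(model$coeffs)[2]
  ntot <- n_samples + burn_in
  L <- t(chol(model$noise_cov))
  x <- L %*% matrix(rnorm(m * ntot), m, ntot)  # innovations, then recurse
  if (m == 1) {                                # fast scalar-AR path
    y <- stats::filter(drop(x), drop(model$coeffs), method = "recursive")
    return(matrix(y[(burn_in + 1):ntot], 1))
  }
  A <- lapply(seq_len(p), function(r) model$coeffs[r, , ])
  for (t in (p + 1):ntot) {
    acc <- x[, t]
    for (r in seq_len(p)) acc <- acc + A[[r]] %*% x[, t - r]
    x[, t] <- acc
  }
  x[, (burn_in + 1):ntot, drop = FALSE]
}

default_block_scale <- function(group) {
  switch(group,
         vigilance   = c(1.0, 0.7, 0.4),
         enhancement = c(1.0, 1.0, 0.95),
         stop("unknown group: ", group))
}

#' Simulate a full synthetic EEG session
#'
#' Generates three concatenated time-on-task blocks from per-block MVAR
#' models. In the vigilance group the coupling weakens across blocks
#' (default block scales 1.0, 0.7, 0.4); in the enhancement group it is
#' maintained (1.0, 1.0, 0.95). Target-onset events are placed evenly so the
#' requested number of epochs fits in each block, independent Gaussian sensor
#' noise is added, and the ground-truth coupling used per block is stored.
#'
#' @param group `"vigilance"` or `"enhancement"`; sets the default block
#'   scales when `spec$block_scale` is `NULL`.
#' @param spec a [coupling_spec()]; default [default_coupling_spec()].
#' @param fs sampling rate in Hz (must be positive).
#' @param seed optional RNG seed.
#' @param block_minutes duration of each block in minutes.
#' @param epoch_ms epoch length in milliseconds (used to place events).
#' @param epochs_per_block events per block; default 450 (at most the number
#'   of non-overlapping epochs that fit).
#' @param sensor_noise additive white sensor noise, as a fraction of the
#'   signal standard deviation (default 0.05).
#' @param block_jitter half-width of a uniform multiplicative jitter on each
#'   block's scale (within-subject between-block variability); default 0.
#' @param noise_sd innovation standard deviation (microvolts).
#' @param channel_labels channel names; defaults to the 62-channel 10-20
#'   montage names when `spec$n_channels == 62`, else `ch1..chm`.
#' @return an object of class `session_recording` with elements `signal`
#'   (channels x samples, microvolts), `fs`, `channel_labels`, `events`
#'   (target-onset sample indices), `block_bounds` (3 x 2 matrix of first/last
#'   samples), `group` and `truth` (spec, effective block scales, per-block
#'   models).
#' @export
simulate_session <- function(group = c("vigilance", "enhancement"),
                             spec = default_coupling_spec(),
                             fs = 500, seed = NULL,
                             block_minutes = 20, epoch_ms = 1200,
                             epochs_per_block = NULL,
                             sensor_noise = 0.05, block_jitter = 0,
                             noise_sd = 10, channel_labels = NULL) {
  group <- match.arg(group)
  if (fs <= 0) stop("config error: fs must be positive")
  if (!is.null(seed)) set.seed(seed)
  scales <- spec$block_scale
  if (is.null(scales)) scales <- default_block_scale(group)
  n_blocks <- length(scales)
  if (block_jitter > 0)
    scales <- scales * (1 + runif(n_blocks, -block_jitter, block_jitter))
  spec_eff <- spec; spec_eff$block_scale <- scales

  m <- spec$n_channels
  block_len <- round(block_minutes * 60 * fs)
  ep_len <- round(epoch_ms / 1000 * fs)
  max_fit <- floor(block_len / ep_len)
  if (is.null(epochs_per_block)) epochs_per_block <- min(450L, max_fit)
  if (epochs_per_block > max_fit)
    stop("config error: ", epochs_per_block, " epochs of ", ep_len,
         " samples do not fit in a ", block_len, "-sample block")
  spacing <- floor(block_len / epochs_per_block)

  models <- vector("list", n_blocks)
  signal <- matrix(0, m, block_len * n_blocks)
  events <- integer(0)
  block_bounds <- matrix(0L, n_blocks, 2,
                         dimnames = list(NULL, c("first", "last")))
  for (b in seq_len(n_blocks)) {
    models[[b]] <- make_var_model(spec_eff, b, noise_sd = noise_sd)
    off <- (b - 1) * block_len
    signal[, off + seq_len(block_len)] <-
      simulate_var(models[[b]], block_len, burn_in = 500L)
    ev <- off + (seq_len(epochs_per_block) - 1L) * spacing + 1L
    events <- c(events, ev[ev + ep_len - 1L <= off + block_len])
    block_bounds[b, ] <- c(off + 1L, off + block_len)
  }
  if (sensor_noise > 0)
    signal <- signal + sensor_noise * sd(signal) *
      matrix(rnorm(length(signal)), nrow = m)
  if (is.null(channel_labels)) {
    channel_labels <- if (m == 62) montage_10_20_62()$channel
                      else paste0("ch", seq_len(m))
  }
  structure(list(signal = signal, fs = fs, channel_labels = channel_labels,
                 events = as.integer(events), block_bounds = block_bounds,
                 group = group,
                 truth = list(spec = spec, block_scale = scales,
                              models = models)),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %d channels x %d samples @ %g Hz (%s)\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              if (is.null(x$group)) "unlabelled" else x$group))
  cat(sprintf("  %d events, %d blocks\n", length(x$events),
              if (is.null(x$block_bounds)) 1L else nrow(x$block_bounds)))
  invisible(x)
}

#' Simulate behavioural time-on-task series
#'
#' Produces per-bin reaction time, accuracy, and omission/commission rates
#' over a session divided into equal bins (default twenty 3-minute bins over
#' 60 minutes). Vigilance shows a linear reaction-time increase and accuracy
#' decline with time-on-task; enhancement shows a mild reaction-time decrease
#' with accuracy maintained.
#'
#' @param group `"vigilance"` or `"enhancement"`.
#' @param n_bins number of bins (>= 2).
#' @param seed optional RNG seed.
#' @param session_minutes session duration; bin spacing is
#'   `session_minutes / n_bins` minutes.
#' @param rt_base baseline reaction time in seconds.
#' @param rt_slope reaction-time slope in s/min; default +0.002 (vigilance)
#'   or -0.001 (enhancement).
#' @param rt_noise Gaussian noise SD on per-bin reaction time (seconds).
#' @param acc_base baseline accuracy fraction.
#' @param acc_slope accuracy slope per minute; default -0.0025 (vigilance) or
#'   +0.0003 (enhancement).
#' @param acc_noise Gaussian noise SD on per-bin accuracy.
#' @return object of class `behavior_series`: data frame with columns
#'   `bin_time` (minutes), `reaction_time` (s), `accuracy`, `omission_rate`,
#'   `commission_rate`.
#' @export
simulate_behavior <- function(group = c("vigilance", "enhancement"),
                              n_bins = 20, seed = NULL, session_minutes = 60,
                              rt_base = 0.5, rt_slope = NULL,
                              rt_noise = 0.02, acc_base = 0.95,
                              acc_slope = NULL, acc_noise = 0.01) {
  group <- match.arg(group)
  stopifnot(n_bins >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rt_slope))
    rt_slope <- if (group == "vigilance") 0.002 else -0.001
  if (is.null(acc_slope))
    acc_slope <- if (group == "vigilance") -0.0025 else 0.0003
  tmin <- (seq_len(n_bins)) * (session_minutes / n_bins)
  rt <- pmax(rt_base + rt_slope * tmin + rnorm(n_bins, 0, rt_noise), 0.05)
  acc <- pmin(pmax(acc_base + acc_slope * tmin + rnorm(n_bins, 0, acc_noise),
                   0), 1)
  omis <- pmin(pmax((1 - acc) * 0.6 + rnorm(n_bins, 0, acc_noise / 2), 0), 1)
  comm <- pmin(pmax((1 - acc) * 0.3 + rnorm(n_bins, 0, acc_noise / 2), 0), 1)
  structure(data.frame(bin_time = tmin, reaction_time = rt, accuracy = acc,
                       omission_rate = omis, commission_rate = comm,
                       group = group),
            class = c("behavior_series", "data.frame"))
}

#' Jitter a coupling specification's edge strengths
#'
#' Applies independent uniform multiplicative jitter to every edge strength,
#' emulating between-subject variability of connectivity.
#'
#' @param spec a [coupling_spec()].
#' @param jitter half-width of the uniform multiplier (default 0.10 for
#'   +/-10 percent).
#' @param seed optional RNG seed.
#' @return a jittered `coupling_spec`.
#' @export
jitter_spec <- function(spec, jitter = 0.10, seed = NULL) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (nrow(spec$edges) > 0)
    spec$edges$strength <- spec$edges$strength *
      (1 + runif(nrow(spec$edges), -jitter, jitter))
  spec
}
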