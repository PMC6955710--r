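#' Write a connectivity matrix to a delimited file
#'
#' Tab-separated matrix with channel names, preceded by comment lines naming
#' the orientation ("row=receiver, column=sender"), the frequency band and
#' the number of epochs averaged.
#'
#' @param cm a `connectivity_matrix`.
#' @param path output file.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  labels <- cm$channel_labels %||% paste0("ch", seq_len(nrow(cm$W)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# orientation: row=receiver, column=sender",
               sprintf("# band_hz: %g %g", cm$band[1], cm$band[2]),
               sprintf("# n_epochs: %d", cm$n_epochs_averaged)), con)
  W <- cm$W; dimnames(W) <- list(labels, labels)
  write.table(W, con, sep = "\t", quote = FALSE, col.names = NA)
}

#' Read a connectivity matrix written by [write_connectivity()]
#' @param path input file.
#' @return a `connectivity_matrix`.
#' @export
read_connectivity <- function(path) {
  hdr <- readLines(path, n = 3)
  band <- as.numeric(strsplit(sub("# band_hz: ", "", hdr[2]), " ")[[1]])
  n_ep <- as.integer(sub("# n_epochs: ", "", hdr[3]))
  W <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                            comment.char = "#", row.names = 1,
                            check.names = FALSE))
  connectivity_matrix(W, band = band, n_epochs_averaged = n_ep,
                      channel_labels = rownames(W))
}

#' Write a session recording to a plain-text container
#'
#' The signal goes to `<path>.tsv` (samples x channels, tab-separated, header
#' = channel labels) and the metadata to a `<path>.meta` sidecar of
#' `key = value` lines (sampling rate, events, block bounds, group). The
#' ground-truth coupling, when present, is written by [write_truth_edges()].
#'
#' @param rec a `session_recording`.
#' @param path base path (without extension).
#' @return invisibly, the two file paths.
#' @export
write_session <- function(rec, path) {
  sig_path <- paste0(path, ".tsv"); meta_path <- paste0(path, ".meta")
  sig <- t(rec$signal)
  colnames(sig) <- rec$channel_labels
  write.table(sig, sig_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(sprintf("fs = %g", rec$fs),
            sprintf("group = %s", rec$group %||% "NA"),
            sprintf("events = %s", paste(rec$events, collapse = ",")),
            sprintf("block_first = %s",
                    paste(rec$block_bounds[, 1], collapse = ",")),
            sprintf("block_last = %s",
                    paste(rec$block_bounds[, 2], collapse = ",")))
  writeLines(meta, meta_path)
  invisible(c(sig_path, meta_path))
}

#' Read a session recording written by [write_session()]
#' @param path base path (without extension).
#' @return a `session_recording` (without ground truth).
#' @export
read_session <- function(path) {
  sig <- as.matrix(read.table(paste0(path, ".tsv"), sep = "\t",
                              header = TRUE, check.names = FALSE))
  meta <- readLines(paste0(path, ".meta"))
  get <- function(key) sub(paste0("^", key, " = "), "",
                           grep(paste0("^", key, " = "), meta, value = TRUE))
  num <- function(key) as.numeric(strsplit(get(key), ",")[[1]])
  structure(list(signal = t(sig), fs = num("fs"),
                 channel_labels = colnames(sig),
                 events = as.integer(num("events")),
                 block_bounds = cbind(first = as.integer(num("block_first")),
                                      last = as.integer(num("block_last"))),
                 group = get("group"), truth = NULL),
            class = "session_recording")
}

#' Write the ground-truth directed edge list of a session
#'
#' One row per edge and block: `source`, `target`, `strength` (block-scaled),
#' `block`, tab-separated.
#'
#' @param rec a `session_recording` with stored `truth`.
#' @param path output file.
#' @export
write_truth_edges <- function(rec, path) {
  tr <- rec$truth
  if (is.null(tr)) stop("session has no stored ground truth")
  rows <- do.call(rbind, lapply(seq_along(tr$block_scale), function(b)
    cbind(tr$spec$edges[, c("source", "target")],
          strength = tr$spec$edges$strength * tr$block_scale[b], block = b)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read or write a montage file
#'
#' Delimited file with columns `channel` and `hemisphere`.
#'
#' @param path montage file.
#' @return data frame with columns `channel`, `hemisphere`.
#' @export
read_montage <- function(path) {
  mt <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "hemisphere") %in% names(mt)))
  mt
}

#' @rdname read_montage
#' @param montage data frame with columns `channel`, `hemisphere`.
#' @export
write_montage <- function(montage, path) {
  write.table(montage[, c("channel", "hemisphere")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
}

# ---- European Data Format (EDF, 16-bit) ---------------------------------

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

#' Write a recording to European Data Format
#'
#' Minimal EDF writer: one fixed-duration data record per `record_seconds`,
#' 16-bit samples with per-channel physical scaling spanning the observed
#' range. The trailing partial record, if any, is zero-padded.
#'
#' @param rec a recording with `signal` (channels x samples, microvolts),
#'   `fs` and `channel_labels`.
#' @param path output `.edf` file.
#' @param record_seconds data-record duration (default 1 s).
#' @export
write_edf <- function(rec, path, record_seconds = 1) {
  sig <- rec$signal
  m <- nrow(sig); n <- ncol(sig)
  spr <- round(rec$fs * record_seconds)           # samples per record
  n_rec <- ceiling(n / spr)
  if (n_rec * spr > n)
    sig <- cbind(sig, matrix(0, m, n_rec * spr - n))
  pmin_ <- apply(sig, 1, min); pmax_ <- apply(sig, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(edf_pad("0", 8), edf_pad("synthetic subject", 80),
                edf_pad("synthetic recording", 80),
                edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
                edf_pad(256 + 256 * m, 8), edf_pad("", 44),
                edf_pad(n_rec, 8), edf_pad(record_seconds, 8),
                edf_pad(m, 4))
  labels <- rec$channel_labels %||% paste0("ch", seq_len(m))
  fields <- paste0(
    paste(edf_pad(labels, 16), collapse = ""),
    paste(edf_pad(rep("", m), 80), collapse = ""),
    paste(edf_pad(rep("uV", m), 8), collapse = ""),
    paste(edf_pad(sprintf("%.6g", pmin_), 8), collapse = ""),
    paste(edf_pad(sprintf("%.6g", pmax_), 8), collapse = ""),
    paste(edf_pad(rep(dmin, m), 8), collapse = ""),
    paste(edf_pad(rep(dmax, m), 8), collapse = ""),
    paste(edf_pad(rep("", m), 80), collapse = ""),
    paste(edf_pad(rep(spr, m), 8), collapse = ""),
    paste(edf_pad(rep("", m), 32), collapse = ""))
  writeChar(paste0(hdr, fields), con, eos = NULL)
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(m)) {
      dig <- round((sig[ch, idx] - pmin_[ch]) * gain[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a European Data Format file
#'
#' Minimal EDF reader matching [write_edf()]: fixed-layout ASCII header,
#' 16-bit little-endian samples, physical scaling from the per-channel
#' digital/physical ranges. All channels must share one sampling rate.
#'
#' @param path `.edf` file.
#' @return a `session_recording` with `signal`, `fs`, `channel_labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(k) trimws(readChar(con, k, useBytes = TRUE))
  invisible(rd(8 + 80 + 80 + 8 + 8))
  invisible(rd(8)); invisible(rd(44))
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  m <- as.integer(rd(4))
  labels <- vapply(seq_len(m), function(i) rd(16), character(1))
  invisible(rd(80 * m)); invisible(rd(8 * m))
  pmin_ <- as.numeric(vapply(seq_len(m), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(m), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(m), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(m), function(i) rd(8), character(1)))
  invisible(rd(80 * m))
  spr <- as.integer(vapply(seq_len(m), function(i) rd(8), character(1)))
  invisible(rd(32 * m))
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates not supported")
  sig <- matrix(0, m, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(m)) {
      dig <- readBin(con, integer(), n = spr[1], size = 2, endian = "little")
      sig[ch, idx] <- pmin_[ch] +
        (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
    }
  }
  structure(list(signal = sig, fs = spr[1] / rec_dur,
                 channel_labels = labels, events = NULL,
                 block_bounds = NULL, group = NULL, truth = NULL),
            class = "session_recording")
}
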