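#' Default 62-channel 10-20 montage with hemisphere labels
#'
#' The standard extended 10-20 64-electrode layout minus the mastoids
#' (M1/M2): 27 left-hemisphere channels, 27 right-hemisphere channels, and 8
#' midline channels (Fpz, Fz, FCz, Cz, CPz, Pz, POz, Oz). The non-standard
#' label "PT8" occasionally seen for the posterior temporal site maps to TP8
#' in this montage.
#'
#' @return data frame with columns `channel` and `hemisphere`
#'   (`"left"`, `"right"` or `"midline"`).
#' @export
montage_10_20_62 <- function() {
  ch <- c("Fp1", "Fpz", "Fp2", "AF3", "AF4",
          "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
          "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
          "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
          "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
          "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
          "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
          "CB1", "O1", "Oz", "O2", "CB2")
  data.frame(channel = ch, hemisphere = infer_hemisphere(ch))
}

#' Infer hemisphere from a 10-20 electrode label
#'
#' Labels ending in `z`/`Z` are midline; otherwise the trailing number
#' decides: odd = left, even = right.
#'
#' @param labels character vector of electrode names.
#' @return character vector of `"left"`, `"right"`, `"midline"`.
#' @export
infer_hemisphere <- function(labels) {
  vapply(labels, function(lab) {
    if (grepl("z$", lab, ignore.case = TRUE)) return("midline")
    num <- regmatches(lab, regexpr("[0-9]+$", lab))
    if (length(num) == 0) stop("cannot infer hemisphere from label: ", lab)
    if (as.integer(num) %% 2 == 1) "left" else "right"
  }, character(1), USE.NAMES = FALSE)
}

#' Split a connectivity matrix into hemispheric sub-networks
#'
#' Drops midline channels and partitions the remaining entries into the four
#' sender -> receiver blocks LL (left to left), LR (left to right), RR and
#' RL. Under the row = receiver convention the block `X -> Y` holds
#' `W[receiver in Y, sender in X]`.
#'
#' @param W a `connectivity_matrix` or named weight matrix.
#' @param montage data frame with columns `channel`, `hemisphere` covering
#'   every channel of `W`; default [montage_10_20_62()].
#' @return list with the four sub-matrices `LL`, `LR`, `RL`, `RR` (rows =
#'   receivers, columns = senders) and the channel sets `left`, `right`.
#' @export
split_hemispheres <- function(W, montage = montage_10_20_62()) {
  cm_labels <- if (inherits(W, "connectivity_matrix")) W$channel_labels
               else rownames(W)
  W <- as_weight_matrix(W)
  if (is.null(cm_labels)) stop("labelling error: connectivity matrix has no channel labels")
  if (!all(cm_labels %in% montage$channel))
    stop("labelling error: channels missing from montage: ",
         paste(setdiff(cm_labels, montage$channel), collapse = ", "))
  hemi <- montage$hemisphere[match(cm_labels, montage$channel)]
  left <- which(hemi == "left"); right <- which(hemi == "right")
  if (length(left) == 0 || length(right) == 0)
    stop("labelling error: need channels in both hemispheres")
  dimnames(W) <- list(cm_labels, cm_labels)
  list(LL = W[left, left, drop = FALSE],
       LR = W[right, left, drop = FALSE],   # senders left, receivers right
       RL = W[left, right, drop = FALSE],
       RR = W[right, right, drop = FALSE],
       left = cm_labels[left], right = cm_labels[right])
}

#' Hemispheric information flow of a sub-network block
#'
#' Per-sender total outflow: each sender column of the block is summed over
#' its receivers. The complementary per-receiver inflow is also returned,
#' since "total information flow from one node to all other nodes" can be
#' read either way.
#'
#' @param sub a sub-matrix from [split_hemispheres()] (rows = receivers,
#'   columns = senders).
#' @return list with `outflow` (per sender) and `inflow` (per receiver),
#'   both named numeric vectors, and `total` (sum of all block weights).
#' @export
hif <- function(sub) {
  sub <- as.matrix(sub)
  list(outflow = colSums(sub), inflow = rowSums(sub), total = sum(sub))
}

#' Laterality index
#'
#' `(LH - RH) / (LH + RH)`, in \[-1, 1\]: positive values indicate
#' left-hemisphere dominance of the summarised quantity.
#'
#' @param lh_value,rh_value left/right hemisphere summaries (e.g. mean
#'   normalised degree or total HIF); `lh + rh` must be nonzero.
#' @return scalar in \[-1, 1\].
#' @export
laterality_index <- function(lh_value, rh_value) {
  if (lh_value + rh_value == 0)
    stop("undefined laterality index: LH + RH = 0")
  (lh_value - rh_value) / (lh_value + rh_value)
}

#' Hemispheric information-flow report for one connectivity matrix
#'
#' @inheritParams split_hemispheres
#' @return data frame (long) with columns `quadrant` (LL/LR/RL/RR), `node`
#'   (sender), `flow` (outflow), plus attribute `laterality` = laterality
#'   index of total within-hemisphere flow (LL vs RR).
#' @export
hif_report <- function(W, montage = montage_10_20_62()) {
  blocks <- split_hemispheres(W, montage)
  rows <- do.call(rbind, lapply(c("LL", "LR", "RL", "RR"), function(q) {
    fl <- hif(blocks[[q]])$outflow
    data.frame(quadrant = q, node = names(fl), flow = unname(fl))
  }))
  attr(rows, "laterality") <- laterality_index(sum(blocks$LL), sum(blocks$RR))
  rows
}
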