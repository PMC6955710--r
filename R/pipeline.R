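#' Pipeline configuration
#'
#' Collects every tunable setting of the end-to-end cohort pipeline with
#' defaults matching the study design: 500 Hz sampling, 1200 ms target-locked
#' epochs, MVAR order 7, PDC band 0.5-30 Hz on a 0.5 Hz grid, absolute
#' thresholds 0/0.1/0.15/0.2/0.25/0.3, sparsities 0.10-0.30 in steps of 0.05,
#' three 20-minute time-on-task blocks, alpha 0.05, and 12 subjects per
#' group. Reduce `n_channels`, `epochs_per_block` and `block_minutes` for
#' desk-scale runs.
#'
#' @param n_channels channels per subject (62 in the study).
#' @param n_subjects subjects per group.
#' @param fs sampling rate (Hz).
#' @param epoch_ms epoch length (ms).
#' @param order MVAR order (or `"aic"`).
#' @param band PDC averaging band (Hz).
#' @param freqs PDC frequency grid (Hz).
#' @param thresholds absolute threshold grid.
#' @param sparsities proportional sparsity grid.
#' @param block_minutes minutes per time-on-task block.
#' @param epochs_per_block target epochs per block (`NULL` = as many 1200 ms
#'   epochs as fit, capped at 450).
#' @param amp_limit epoch rejection limit (microvolts).
#' @param ridge relative ridge penalty for the MVAR fit; the default `1e-6`
#'   accommodates the exact rank deficiency introduced by common-average
#'   referencing.
#' @param car apply common average reference.
#' @param filter_band `c(lo, hi)` FIR band-pass in Hz, or `NULL` to skip
#'   filtering (the default for model-generated sessions, which are already
#'   band-limited; heavy low-pass filtering of oversampled data degrades
#'   finite-order MVAR estimates).
#' @param alpha significance level.
#' @param tmap_threshold electrode t-map significance criterion.
#' @param subject_jitter between-subject edge-strength jitter (half-width of
#'   the uniform multiplier).
#' @param block_jitter within-subject between-block scale jitter.
#' @param n_bins behavioural bins per session (20 x 3 min in the study).
#' @param seed master seed; all stage seeds derive from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_channels = 62, n_subjects = 12, fs = 500,
                       epoch_ms = 1200, order = 7L, band = c(0.5, 30),
                       freqs = seq(0.5, 30, by = 0.5),
                       thresholds = c(0, 0.1, 0.15, 0.2, 0.25, 0.3),
                       sparsities = seq(0.10, 0.30, by = 0.05),
                       block_minutes = 20, epochs_per_block = NULL,
                       amp_limit = 100, ridge = 1e-6, car = TRUE,
                       filter_band = NULL, alpha = 0.05,
                       tmap_threshold = 2.5, subject_jitter = 0.10,
                       block_jitter = 0.12, n_bins = 20, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$fs > 0, cfg$n_subjects >= 2, cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k,
                                  paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}

# preprocess one session per the config: CAR, optional band-pass, epoching,
# baseline removal, amplitude rejection
preprocess_session <- function(sess, config) {
  if (isTRUE(config$car)) sess <- rereference_car(sess)
  if (!is.null(config$filter_band))
    sess <- bandpass_fir(sess, config$filter_band[1], config$filter_band[2])
  ep <- epoch_and_baseline(sess, epoch_ms = config$epoch_ms)
  reject_epochs(ep, config$amp_limit)
}

# per-subject, per-block summaries used by the group statistics
summarise_blocks <- function(epochs, config, montage) {
  blocks <- sort(unique(epochs$block_labels[epochs$kept_mask]))
  m <- dim(epochs$data)[2]
  thr <- config$thresholds[config$thresholds > 0]
  out <- lapply(blocks, function(b) {
    cm <- block_connectivity(epochs, b, p = config$order,
                             ridge = config$ridge, freqs = config$freqs,
                             band = config$band)
    rep_ <- graph_metrics_report(cm, config$thresholds, config$sparsities)
    nd <- rep_$nodal[rep_$nodal$threshold %in% thr, ]
    per_node_deg <- tapply(nd$norm_degree, nd$node, mean)  # over thresholds
    hr <- hif_report(cm, montage)
    list(block = b,
         mean_norm_degree = mean(nd$norm_degree),
         mean_strength = mean(nd$strength),
         CC_int = rep_$integrals[["CC_int"]],
         PL_int = rep_$integrals[["PL_int"]],
         laterality = attr(hr, "laterality"),
         electrode_degree = per_node_deg,
         hif = hr,
         connectivity = cm)
  })
  names(out) <- paste0("block", blocks)
  out
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a vigilance and an enhancement cohort, preprocesses every
#' session, estimates per-block PDC connectivity, computes graph and
#' hemispheric summaries, and runs the group statistics: Holm-corrected
#' paired contrasts across time-on-task levels within each group, Welch
#' contrasts between groups at each level, per-electrode t-maps, and the
#' one-vs-all degree-change vs reaction-time-change correlation per level.
#'
#' All randomness derives from `config$seed`; re-running with the same
#' config reproduces all numeric outputs.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all result tables plus a
#'   JSON run manifest are written there.
#' @param dry_run validate the config and return the stage plan without
#'   touching data.
#' @return a report list with elements `subject_table` (per subject x block
#'   global metrics), `comparisons` (all contrasts with Holm-adjusted p),
#'   `tmaps`, `correlations`, `behavior`, `electrode_degree`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- c("simulate", "preprocess", "connect", "graph", "hemi", "stats")
  if (dry_run) return(list(stages = stages, config = config))

  groups <- c("vigilance", "enhancement")
  base_spec <- default_coupling_spec(config$n_channels,
                                     seed = config$seed %% 2147483647L)
  labels <- if (config$n_channels == 62) montage_10_20_62()$channel
            else paste0("ch", seq_len(config$n_channels))
  montage <- data.frame(channel = labels,
                        hemisphere = infer_hemisphere(labels))

  subj <- list(); behav <- list()
  for (gi in seq_along(groups)) {
    for (s in seq_len(config$n_subjects)) {
      sseed <- (config$seed + 7919L * gi + 104729L * s) %% 2147483647L
      spec_s <- jitter_spec(base_spec, config$subject_jitter, seed = sseed)
      sess <- simulate_session(groups[gi], spec_s, fs = config$fs,
                               seed = sseed + 1L,
                               block_minutes = config$block_minutes,
                               epoch_ms = config$epoch_ms,
                               epochs_per_block = config$epochs_per_block,
                               block_jitter = config$block_jitter,
                               channel_labels = labels)
      ep <- preprocess_session(sess, config)
      subj[[paste(groups[gi], s)]] <-
        c(list(group = groups[gi], subject = s),
          list(blocks = summarise_blocks(ep, config, montage)))
      behav[[paste(groups[gi], s)]] <-
        simulate_behavior(groups[gi], n_bins = config$n_bins,
                          seed = sseed + 2L,
                          session_minutes = config$block_minutes *
                            length(sess$truth$block_scale))
    }
  }

  subject_table <- do.call(rbind, lapply(subj, function(x)
    do.call(rbind, lapply(x$blocks, function(b)
      data.frame(group = x$group, subject = x$subject, block = b$block,
                 mean_norm_degree = b$mean_norm_degree,
                 mean_strength = b$mean_strength, CC_int = b$CC_int,
                 PL_int = b$PL_int, laterality = b$laterality)))))
  rownames(subject_table) <- NULL

  metrics <- c("mean_norm_degree", "mean_strength", "CC_int", "PL_int")
  getvals <- function(group, block, metric)
    subject_table[subject_table$group == group &
                    subject_table$block == block, metric]
  contrasts <- rbind(
    expand.grid(group = groups, a = 1:2, b = 2:3,
                stringsAsFactors = FALSE))
  contrasts <- contrasts[contrasts$a < contrasts$b, ]
  comp <- list()
  for (i in seq_len(nrow(contrasts))) {
    g <- contrasts$group[i]; a <- contrasts$a[i]; b <- contrasts$b[i]
    lab <- sprintf("%s L%d vs L%d", g, a, b)
    for (mt in metrics) {
      tt <- pairwise_ttest(getvals(g, a, mt), getvals(g, b, mt),
                           paired = TRUE)
      comp[[length(comp) + 1]] <- data.frame(contrast = lab, metric = mt,
                                             t = tt$t, p = tt$p, df = tt$df)
    }
  }
  for (b in 1:3) for (mt in metrics) {
    tt <- pairwise_ttest(getvals("vigilance", b, mt),
                         getvals("enhancement", b, mt), paired = FALSE)
    comp[[length(comp) + 1]] <- data.frame(
      contrast = sprintf("V%d vs E%d", b, b), metric = mt,
      t = tt$t, p = tt$p, df = tt$df)
  }
  comparisons <- do.call(rbind, comp)
  hc <- holm_correct(comparisons$p, config$alpha)
  comparisons$p_holm <- hc$adjusted
  comparisons$significant <- hc$reject

  # per-electrode normalised degree, subjects x electrodes, per group/block
  edeg <- function(group, block) {
    rows <- lapply(subj, function(x)
      if (x$group == group) x$blocks[[paste0("block", block)]]$electrode_degree)
    mat <- do.call(rbind, Filter(Negate(is.null), rows))
    colnames(mat) <- labels
    mat
  }
  tmaps <- list()
  for (b in 1:3)
    tmaps[[sprintf("V%d vs E%d", b, b)]] <-
      electrode_tmap(edeg("vigilance", b), edeg("enhancement", b),
                     paired = FALSE, t_threshold = config$tmap_threshold)
  tmaps[["vigilance L1 vs L3"]] <-
    electrode_tmap(edeg("vigilance", 1), edeg("vigilance", 3),
                   paired = TRUE, t_threshold = config$tmap_threshold)

  # degree-change vs reaction-time-change, one-vs-all per level
  rt_level <- function(group, block) {
    vapply(names(behav)[startsWith(names(behav), group)], function(nm) {
      bs <- behav[[nm]]
      lo <- (block - 1) * config$block_minutes
      hi <- block * config$block_minutes
      mean(bs$reaction_time[bs$bin_time > lo & bs$bin_time <= hi])
    }, numeric(1))
  }
  correlations <- do.call(rbind, lapply(1:3, function(b) {
    dd <- delta_one_vs_all(getvals("enhancement", b, "mean_norm_degree"),
                           getvals("vigilance", b, "mean_norm_degree"))
    dr <- delta_one_vs_all(rt_level("enhancement", b),
                           rt_level("vigilance", b))
    ct <- correlate_delta(dd, dr)
    data.frame(level = b, n = ct$n, r = ct$r, p = ct$p)
  }))

  report <- list(subject_table = subject_table, comparisons = comparisons,
                 tmaps = tmaps, correlations = correlations,
                 behavior = behav,
                 electrode_degree = lapply(1:3, function(b)
                   list(vigilance = edeg("vigilance", b),
                        enhancement = edeg("enhancement", b))),
                 config = config)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, nm) write.table(x, file.path(out_dir, nm), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(report$subject_table, "subject_metrics.tsv")
  wt(report$comparisons, "comparisons.tsv")
  wt(report$correlations, "correlations.tsv")
  for (nm in names(report$tmaps))
    wt(report$tmaps[[nm]], paste0("tmap_", gsub("[^A-Za-z0-9]+", "_", nm),
                                  ".tsv"))
  manifest <- list(package = "pdcnet",
                   version = as.character(utils::packageVersion("pdcnet")),
                   config = unclass(report$config),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
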