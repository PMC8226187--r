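# Orchestration: one JSON config drives simulate -> analyze -> report, and
# reports from several conditions can be compared against a designated
# ground-truth condition.

#' Build a run configuration
#'
#' @param mode `"simulate"` (write a synthetic performance to disk),
#'   `"analyze"` (read MIDI/TSV inputs and analyze) or `"full"`
#'   (simulate in memory, then analyze).
#' @param condition condition label (e.g. `"human"`, `"avatar"`,
#'   `"agent"`).
#' @param seed integer seed (required for simulate/full).
#' @param score a [score_spec()].
#' @param p1,p2 [performer_params()] for the two parts.
#' @param motion a [motion_params()].
#' @param si_window_s,si_hop_s,si_threshold,min_segment_s segmentation
#'   parameters (see [synchronization_index()], [segment_by_si()]).
#' @param rqa_phase [rqa_config()] for the phase-series joint RQA.
#' @param rqa_sway [rqa_config()] for the sway recurrence plot.
#' @param fs_phase phase-series sampling rate, Hz.
#' @param coherence_fs rate to which head PC1 series are decimated before
#'   wavelet coherence, Hz.
#' @param inputs named list of input paths for analyze mode
#'   (`midi_top`, `midi_bottom`, optional `head_tsv`, `nods_csv`).
#' @param out_dir output directory (`NULL` = no files written).
#' @return an object of class `run_config`.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       condition = "human", seed = 1L,
                       score = score_spec(),
                       p1 = performer_params("timekeeper"),
                       p2 = performer_params("shifter"),
                       motion = motion_params(),
                       si_window_s = 10, si_hop_s = 0.05,
                       si_threshold = 0.99, min_segment_s = 2.0,
                       rqa_phase = rqa_config(),
                       rqa_sway = rqa_config(m = 5L, tau_s = 0.35),
                       fs_phase = 20, coherence_fs = 20,
                       inputs = list(), out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("simulate", "full") && is.null(seed))
    .stop_config("seed", "is required for simulate/full mode")
  if (mode == "analyze") {
    for (f in c("midi_top", "midi_bottom")) {
      if (is.null(inputs[[f]]))
        .stop_config(paste0("inputs$", f), "is required for analyze mode")
      if (!file.exists(inputs[[f]]))
        stop("path error: no such file: ", inputs[[f]], call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "run_config")
}

.config_hash <- function(config) {
  js <- jsonlite::toJSON(.config_as_list(config), auto_unbox = TRUE,
                         digits = 12)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

.config_as_list <- function(config) {
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    unclass(x)
  }
  strip(config)
}

#' Run the pipeline for one condition
#'
#' Executes the stages requested by the [run_config()]: simulation of the
#' duet (and motion traces), layer-1 analysis (tempo/IOI, relative phase,
#' SI segmentation, windowed joint RQA of the two phase trajectories),
#' layer-2 analysis (head PC1 wavelet coherence with band circular stats,
#' gaze angle, sway recurrence, nod overlay), and writes CSV/JSON
#' artifacts when `out_dir` is set.
#'
#' @param config a [run_config()].
#' @return an object of class `layer_report`: nested list of per-layer
#'   tables plus provenance (`config_hash`, `seed`, package version).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  if (config$mode %in% c("simulate", "full")) {
    perf <- simulate_duet(config$score, config$p1, config$p2,
                          seed = config$seed)
    traces <- synthesize_motion(perf, seed = config$seed,
                                params = config$motion)
    nods <- traces$nods
    if (config$mode == "simulate") {
      if (is.null(config$out_dir))
        .stop_config("out_dir", "is required for simulate mode")
      files <- export_performance(perf, traces, config$out_dir)
      return(invisible(files))
    }
  } else {
    top <- parse_midi(config$inputs$midi_top, "top")
    bottom <- parse_midi(config$inputs$midi_bottom, "bottom")
    perf <- structure(list(streams = list(top = top, bottom = bottom),
                           schedule = NULL, score = config$score,
                           seed = config$seed),
                      class = "duet_performance")
    traces <- NULL
    if (!is.null(config$inputs$head_tsv)) {
      hd <- read_motion_tsv(config$inputs$head_tsv)
      traces <- list(time_s = hd$time_s,
                     head_pos = list(
                       top = as.matrix(hd[, c("top_x", "top_y", "top_z")]),
                       bottom = as.matrix(hd[, c("bottom_x", "bottom_y",
                                                 "bottom_z")])),
                     fs = 1 / stats::median(diff(hd$time_s)))
    }
    nods <- if (!is.null(config$inputs$nods_csv))
      read_nod_annotations(config$inputs$nods_csv) else NULL
  }

  # ---- layer 1 ----
  l1 <- list()
  for (part in c("top", "bottom"))
    l1[[paste0("tempo_", part)]] <-
      tempo_and_ioi(perf$streams[[part]],
                    config$score$sixteenths_per_beat)[
        c("ioi_variability_ms", "tempo_mean_bpm", "tempo_sd_bpm",
          "tempo_median_ioi_bpm")]
  ph1 <- cycle_phase(perf$streams$top, fs = config$fs_phase)
  ph2 <- cycle_phase(perf$streams$bottom, fs = config$fs_phase)
  rel <- relative_phase(ph1, ph2)
  si <- synchronization_index(rel, config$si_window_s, config$si_hop_s)
  segments <- segment_by_si(si, config$si_threshold, config$min_segment_s)
  # joint RQA needs both trajectories on the common grid
  crop <- function(p) {
    keep <- p$time_s >= rel$time_s[1] - 1e-9 &
      p$time_s <= rel$time_s[length(rel$time_s)] + 1e-9
    p$time_s <- p$time_s[keep]; p$phase_rad <- p$phase_rad[keep]
    p
  }
  r1 <- recurrence_matrix(crop(ph1), config$rqa_phase)
  r2 <- recurrence_matrix(crop(ph2), config$rqa_phase)
  jrqa <- rqa_metrics(joint_recurrence(r1, r2), windowed = TRUE)
  l1$segments <- segments
  l1$si <- data.frame(time_s = si$time_s, si = si$si)
  l1$jrqa <- jrqa[c("rr", "det", "tt")]
  l1$jrqa_windowed <- jrqa$windowed

  # ---- layer 2 ----
  l2 <- NULL
  if (!is.null(traces)) {
    dec <- max(1L, round(traces$fs / config$coherence_fs))
    idx <- seq(1L, length(traces$time_s), by = dec)
    pc_top <- head_pc1(traces$head_pos$top[idx, ], fs = traces$fs / dec)
    pc_bot <- head_pc1(traces$head_pos$bottom[idx, ], fs = traces$fs / dec)
    cmap <- wavelet_coherence(pc_top$series, pc_bot$series,
                              fs = traces$fs / dec)
    cstats <- band_phase_stats(cmap)
    peak <- coherence_peak(cmap)
    l2 <- list(coherence_peak_hz = peak$peak_hz,
               band_circular = cstats[c("mean_angle_deg",
                                        "resultant_length")],
               head_var_explained = c(top = pc_top$var_explained,
                                      bottom = pc_bot$var_explained))
    if (!is.null(traces$gaze_dir)) {
      ga <- gaze_angle(traces$gaze_dir, traces$head_pos$top,
                       traces$head_pos$bottom, time_s = traces$time_s)
      l2$gaze <- c(mean_deg = mean(ga$angle_deg, na.rm = TRUE),
                   min_deg = min(ga$angle_deg, na.rm = TRUE))
    }
    if (!is.null(traces$sway_pressure)) {
      sw <- sway_recurrence(traces$sway_pressure, traces$fs,
                            cfg = config$rqa_sway)
      l2$sway <- c(radius = sw$radius, rr = sw$metrics$rr,
                   det = sw$metrics$det, tt = sw$metrics$tt)
    }
    if (!is.null(nods) && nrow(nods))
      l2$nods <- read_nod_annotations_overlay(nods, segments)
  }

  report <- structure(list(
    condition = config$condition,
    layer1 = l1, layer2 = l2, layer3 = NULL,
    provenance = list(config_hash = .config_hash(config),
                      seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("duetphase")),
                      elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                      units = "secs")))),
    class = "layer_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(l1$segments,
                     file.path(config$out_dir, "segments.csv"),
                     row.names = FALSE)
    utils::write.csv(l1$si, file.path(config$out_dir, "si.csv"),
                     row.names = FALSE)
    utils::write.csv(l1$jrqa_windowed,
                     file.path(config$out_dir, "jrqa_windowed.csv"),
                     row.names = FALSE)
    jsonlite::write_json(.report_as_list(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# nod/segment overlay used both from files and from simulated nods
read_nod_annotations_overlay <- function(nods, segments) {
  bounds <- sort(unique(c(segments$start_s, segments$end_s)))
  near <- vapply(nods$time_s, function(t) which.min(abs(bounds - t)), 0L)
  nods$boundary_offset_s <- nods$time_s - bounds[near]
  nods
}

.report_as_list <- function(report) .config_as_list(report)

#' Compare condition reports against a ground truth
#'
#' Side-by-side per-layer summary across conditions with absolute
#' differences from the designated ground-truth condition (the condition
#' labelled `"human"` by default).
#'
#' @param reports list of `layer_report`s from [run_pipeline()].
#' @param ground_truth condition label to difference against.
#' @return data frame of class `condition_comparison`: one row per metric,
#'   one column per condition, plus `abs_diff_<condition>` columns.
#' @export
compare_conditions <- function(reports, ground_truth = "human") {
  stopifnot(length(reports) >= 2L)
  conds <- vapply(reports, function(r) r$condition, "")
  if (anyDuplicated(conds))
    stop("condition labels must be unique", call. = FALSE)
  if (!ground_truth %in% conds) {
    if ("human" %in% conds) ground_truth <- "human"
    else stop("incomparability error: ground-truth condition '",
              ground_truth, "' not among reports", call. = FALSE)
  }
  flatten <- function(r) {
    v <- c(tempo_mean_bpm = r$layer1$tempo_top$tempo_mean_bpm,
           tempo_sd_bpm = r$layer1$tempo_top$tempo_sd_bpm,
           ioi_variability_ms = r$layer1$tempo_top$ioi_variability_ms,
           ioi_variability_bottom_ms =
             r$layer1$tempo_bottom$ioi_variability_ms,
           n_segments = nrow(r$layer1$segments),
           jrqa_rr = r$layer1$jrqa$rr,
           jrqa_det = r$layer1$jrqa$det,
           jrqa_tt = r$layer1$jrqa$tt)
    if (!is.null(r$layer2)) {
      v <- c(v, coherence_peak_hz = r$layer2$coherence_peak_hz,
             band_mean_angle_deg = r$layer2$band_circular$mean_angle_deg,
             band_resultant = r$layer2$band_circular$resultant_length)
      if (!is.null(r$layer2$sway))
        v <- c(v, sway_rr = unname(r$layer2$sway["rr"]))
    }
    if (!is.null(r$layer3))
      v <- c(v, flow_mean = r$layer3$flow_mean)
    v
  }
  rows <- lapply(reports, flatten)
  keys <- Reduce(intersect, lapply(rows, names))
  miss <- Reduce(union, lapply(rows, function(r) setdiff(names(r), keys)))
  if (length(miss))
    warning("metrics not present in every report dropped: ",
            paste(miss, collapse = ", "), call. = FALSE)
  tab <- data.frame(metric = keys)
  for (i in seq_along(reports)) tab[[conds[i]]] <- unname(rows[[i]][keys])
  gt <- tab[[ground_truth]]
  for (cn in setdiff(conds, ground_truth))
    tab[[paste0("abs_diff_", cn)]] <- abs(tab[[cn]] - gt)
  attr(tab, "ground_truth") <- ground_truth
  class(tab) <- c("condition_comparison", "data.frame")
  tab
}
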