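# On-disk formats: Standard MIDI File per performer; tab-separated motion
# tables (header row, first column time_s, UTF-8, LF); nods CSV
# "performer,time_s"; JSON manifest with seed and configuration.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  path
}

#' Export a simulated performance and its motion traces
#'
#' Writes one MIDI file per performer, one TSV per motion signal group, a
#' nods CSV and a JSON manifest (seed + configuration). The files
#' round-trip through [parse_midi()] and [read_motion_tsv()] to within one
#' MIDI tick / full float precision.
#'
#' @param perf a [simulate_duet()] performance.
#' @param traces optional [synthesize_motion()] traces.
#' @param out_dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
export_performance <- function(perf, traces = NULL, out_dir) {
  stopifnot(inherits(perf, "duet_performance"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O failure: cannot create directory ", out_dir, call. = FALSE)
  files <- c(top_midi = file.path(out_dir, "top.mid"),
             bottom_midi = file.path(out_dir, "bottom.mid"),
             manifest = file.path(out_dir, "manifest.json"))
  write_midi(perf$streams$top, files[["top_midi"]],
             tempo_bpm = perf$score$tempo_bpm,
             sixteenths_per_beat = perf$score$sixteenths_per_beat)
  write_midi(perf$streams$bottom, files[["bottom_midi"]],
             tempo_bpm = perf$score$tempo_bpm,
             sixteenths_per_beat = perf$score$sixteenths_per_beat)
  if (!is.null(traces)) {
    stopifnot(inherits(traces, "motion_traces"))
    hp <- traces$head_pos
    files[["head_tsv"]] <- .write_tsv(data.frame(
      time_s = traces$time_s,
      top_x = hp$top[, 1], top_y = hp$top[, 2], top_z = hp$top[, 3],
      bottom_x = hp$bottom[, 1], bottom_y = hp$bottom[, 2],
      bottom_z = hp$bottom[, 3]), file.path(out_dir, "head.tsv"))
    files[["gaze_tsv"]] <- .write_tsv(data.frame(
      time_s = traces$time_s, gx = traces$gaze_dir[, 1],
      gy = traces$gaze_dir[, 2], gz = traces$gaze_dir[, 3]),
      file.path(out_dir, "gaze.tsv"))
    files[["sway_tsv"]] <- .write_tsv(data.frame(
      time_s = traces$time_s, ch1 = traces$sway_pressure[, 1],
      ch2 = traces$sway_pressure[, 2], ch3 = traces$sway_pressure[, 3],
      ch4 = traces$sway_pressure[, 4]), file.path(out_dir, "sway.tsv"))
    files[["pupil_tsv"]] <- .write_tsv(data.frame(
      time_s = traces$time_s, pupil_mm = traces$pupil_mm),
      file.path(out_dir, "pupil.tsv"))
    files[["nods_csv"]] <- file.path(out_dir, "nods.csv")
    utils::write.csv(traces$nods, files[["nods_csv"]], row.names = FALSE,
                     quote = FALSE)
  }
  manifest <- list(seed = perf$seed,
                   score = unclass(perf$score),
                   n_bars = nrow(perf$schedule),
                   motion_params = if (!is.null(traces))
                     unclass(traces$params) else NULL,
                   files = as.list(basename(files)))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}

#' Read a motion TSV
#'
#' Reads the tab-separated motion dialect written by
#' [export_performance()] (header row, first column `time_s`). A column
#' map can adapt third-party exports: a named character vector
#' `c(internal = "external")` renames columns on read.
#'
#' @param path TSV path.
#' @param column_map optional named character vector mapping internal
#'   column names to the file's column names.
#' @return a data frame with strictly increasing `time_s`.
#' @export
read_motion_tsv <- function(path, column_map = NULL) {
  if (!file.exists(path))
    stop("I/O failure: no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE)
  if (!is.null(column_map)) {
    for (internal in names(column_map)) {
      j <- match(column_map[[internal]], names(df))
      if (is.na(j))
        stop("column '", column_map[[internal]], "' not found in ", path,
             call. = FALSE)
      names(df)[j] <- internal
    }
  }
  if (!"time_s" %in% names(df))
    stop("motion TSV must contain a time_s column: ", path, call. = FALSE)
  if (any(diff(df$time_s) <= 0))
    stop("time_s must be strictly increasing: ", path, call. = FALSE)
  df
}

#' Read nod annotations and align them to performance segments
#'
#' Reads a `performer,time_s` CSV of manually annotated head nods. When a
#' [segment_by_si()] table is supplied, each nod is matched to its nearest
#' segment boundary and flagged when it falls outside the segmented span.
#'
#' @param path CSV path.
#' @param segments optional `segment_list` from [segment_by_si()].
#' @return data frame with `performer`, `time_s` and, when segments are
#'   given, `nearest_segment`, `boundary_offset_s`, `out_of_range`.
#' @export
read_nod_annotations <- function(path, segments = NULL) {
  if (!file.exists(path))
    stop("I/O failure: no such file: ", path, call. = FALSE)
  raw_lines <- readLines(path, warn = FALSE)
  if (!length(raw_lines) ||
      (length(raw_lines) == 1L && !nzchar(raw_lines[1])))
    return(data.frame(performer = character(0), time_s = numeric(0)))
  header <- strsplit(raw_lines[1], ",")[[1]]
  if (!all(c("performer", "time_s") %in% header))
    stop("nod CSV must have header 'performer,time_s': ", path,
         call. = FALSE)
  body <- raw_lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",")
  bad <- which(vapply(parts, length, 0L) != length(header) |
                 is.na(suppressWarnings(vapply(parts, function(p)
                   as.numeric(p[match("time_s", header)]), numeric(1)))))
  if (length(bad))
    stop("unparseable nod rows at line(s) ",
         paste(bad + 1L, collapse = ", "), " in ", path, call. = FALSE)
  df <- data.frame(
    performer = vapply(parts, function(p) p[match("performer", header)], ""),
    time_s = vapply(parts, function(p)
      as.numeric(p[match("time_s", header)]), numeric(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(segments)) {
    bounds <- sort(unique(c(segments$start_s, segments$end_s)))
    near <- vapply(df$time_s, function(t) which.min(abs(bounds - t)), 0L)
    df$boundary_offset_s <- df$time_s - bounds[near]
    df$nearest_segment <- vapply(df$time_s, function(t) {
      k <- which(segments$start_s <= t & t <= segments$end_s)
      if (length(k)) k[1] else NA_integer_
    }, 0L)
    df$out_of_range <- df$time_s < min(segments$start_s) |
      df$time_s > max(segments$end_s)
  }
  df
}
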