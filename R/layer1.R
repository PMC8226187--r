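#' Tempo and inter-onset-interval statistics
#'
#' IOIs are successive onset differences; instantaneous tempo converts each
#' IOI to BPM under the dotted-quarter beat (`60 / (sixteenths_per_beat *
#' IOI)`). Tempo is summarised both as the arithmetic mean of the
#' instantaneous series and as the tempo of the median IOI (robust to
#' outliers); IOI variability is the sample SD of IOIs in ms.
#'
#' @param stream a [note_stream()] with at least 13 onsets (one cycle).
#' @param sixteenths_per_beat sixteenths per beat (default 6).
#' @return list with `ioi_ms`, `ioi_variability_ms`, `tempo_bpm`
#'   (instantaneous series), `tempo_mean_bpm`, `tempo_sd_bpm`,
#'   `tempo_median_ioi_bpm`.
#' @export
tempo_and_ioi <- function(stream, sixteenths_per_beat = 6L) {
  stopifnot(inherits(stream, "note_stream"))
  if (length(stream$onsets_s) < 13L)
    stop("insufficient data: need at least 13 onsets", call. = FALSE)
  ioi <- diff(stream$onsets_s)
  tempo <- 60 / (sixteenths_per_beat * ioi)
  list(ioi_ms = ioi * 1000,
       ioi_variability_ms = stats::sd(ioi * 1000),
       tempo_bpm = tempo,
       tempo_mean_bpm = mean(tempo),
       tempo_sd_bpm = stats::sd(tempo),
       tempo_median_ioi_bpm = 60 / (sixteenths_per_beat * stats::median(ioi)))
}

#' Continuous cycle phase from note onsets
#'
#' One full cycle is 12 notes: the k-th onset (k = 0, 1, ...) carries phase
#' `2*pi*k/12`. Phase is linear between onsets, constant outside the onset
#' span, and resampled on a uniform grid.
#'
#' @param stream a [note_stream()] (>= 2 onsets).
#' @param fs sampling rate of the output grid, Hz (default 20).
#' @return an object of class `phase_series`: list with `time_s`,
#'   `phase_rad` (unwrapped, non-decreasing), `fs`.
#' @export
cycle_phase <- function(stream, fs = 20) {
  stopifnot(inherits(stream, "note_stream"))
  on <- stream$onsets_s
  if (length(on) < 2L)
    stop("insufficient data: need at least 2 onsets", call. = FALSE)
  ph <- 2 * pi * (seq_along(on) - 1L) / 12
  t0 <- ceiling(on[1] * fs) / fs
  t1 <- floor(on[length(on)] * fs) / fs
  tt <- seq(t0, t1, by = 1 / fs)
  structure(list(time_s = tt,
                 phase_rad = stats::approx(on, ph, xout = tt, rule = 2,
                                           ties = "ordered")$y,
                 fs = fs),
            class = "phase_series")
}

#' Relative phase between two performers
#'
#' `dphi = phase2 - phase1` on the intersection of the two grids; the
#' wrapped version lies in `[0, 2*pi)` and `offset_sixteenths` is the
#' nearest sixteenth-note offset `round(12 * dphi / 2pi) mod 12`.
#'
#' @param p1,p2 [cycle_phase()] series at the same `fs`.
#' @return an object of class `rel_phase_series`: list with `time_s`,
#'   `dphi_unwrapped`, `dphi_wrapped`, `offset_sixteenths`, `fs`.
#' @export
relative_phase <- function(p1, p2) {
  stopifnot(inherits(p1, "phase_series"), inherits(p2, "phase_series"))
  if (!isTRUE(all.equal(p1$fs, p2$fs)))
    stop("alignment error: sampling rates differ", call. = FALSE)
  fs <- p1$fs
  t0 <- max(p1$time_s[1], p2$time_s[1])
  t1 <- min(p1$time_s[length(p1$time_s)], p2$time_s[length(p2$time_s)])
  if (t1 < t0)
    stop("alignment error: time supports do not overlap", call. = FALSE)
  tt <- seq(ceiling(t0 * fs - 1e-9) / fs, floor(t1 * fs + 1e-9) / fs,
            by = 1 / fs)
  f1 <- stats::approx(p1$time_s, p1$phase_rad, xout = tt, rule = 2,
                      ties = "ordered")$y
  f2 <- stats::approx(p2$time_s, p2$phase_rad, xout = tt, rule = 2,
                      ties = "ordered")$y
  d <- f2 - f1
  dw <- .wrap_2pi(d)
  structure(list(time_s = tt, dphi_unwrapped = d, dphi_wrapped = dw,
                 offset_sixteenths = as.integer(round(12 * dw / (2 * pi)) %% 12),
                 fs = fs),
            class = "rel_phase_series")
}

#' Windowed synchronization index
#'
#' The SI at time t is the circular resultant length of the relative-phase
#' samples in a centered window: `|mean(exp(i * dphi))|`. 1 means the
#' relative phase is constant over the window (phase locked), 0 that it is
#' uniformly dispersed. Edge windows are truncated, never padded.
#'
#' @param rel a [relative_phase()] series.
#' @param window_s window length in seconds (default 10).
#' @param hop_s hop between evaluation points (default 0.05 s).
#' @return an object of class `si_profile`: list with `time_s`, `si`,
#'   `window_s`, `hop_s`, `fs`, and the source `offset_sixteenths` series.
#' @export
synchronization_index <- function(rel, window_s = 10, hop_s = 0.05) {
  stopifnot(inherits(rel, "rel_phase_series"))
  fs <- rel$fs
  if (window_s < 10 / fs)
    stop("window error: window shorter than 10 samples", call. = FALSE)
  n <- length(rel$time_s)
  half <- round(window_s * fs / 2)
  hop <- max(1L, round(hop_s * fs))
  cs <- cumsum(cos(rel$dphi_wrapped))
  sn <- cumsum(sin(rel$dphi_wrapped))
  idx <- seq(1L, n, by = hop)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  prev_c <- cs[pmax(lo - 1L, 1L)]; prev_c[lo == 1L] <- 0
  prev_s <- sn[pmax(lo - 1L, 1L)]; prev_s[lo == 1L] <- 0
  sum_c <- cs[hi] - prev_c
  sum_s <- sn[hi] - prev_s
  cnt <- hi - lo + 1L
  si <- sqrt(sum_c^2 + sum_s^2) / cnt
  structure(list(time_s = rel$time_s[idx], si = pmin(si, 1),
                 offset_sixteenths = rel$offset_sixteenths[idx],
                 window_s = window_s, hop_s = hop / fs, fs = fs),
            class = "si_profile")
}

#' Segment a performance into stable and shifting periods
#'
#' Thresholds the synchronization index: contiguous runs with
#' `si >= threshold` are stable, the rest shifting. Runs shorter than
#' `min_segment_s` are absorbed into a neighbouring run (the longer
#' neighbour wins; ties go to the earlier one). Stable segments are
#' annotated with their modal sixteenth-note offset.
#'
#' @param si an [synchronization_index()] profile.
#' @param threshold SI threshold in (0, 1); 0.99 discriminates the written
#'   measures on the default schedule.
#' @param min_segment_s minimum segment duration in seconds.
#' @return data frame of class `segment_list` with `segment`, `kind`,
#'   `start_s`, `end_s`, `duration_s`, `modal_offset` (NA for shifting).
#' @export
segment_by_si <- function(si, threshold = 0.99, min_segment_s = 2.0) {
  stopifnot(inherits(si, "si_profile"))
  if (!.is_num1(threshold) || threshold <= 0 || threshold >= 1)
    .stop_config("threshold", "must lie in (0, 1)")
  lab <- si$si >= threshold
  dt <- if (length(si$time_s) > 1L) diff(si$time_s[1:2]) else 1
  min_len <- max(1L, round(min_segment_s / dt))
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1L || min(r$lengths) >= min_len) break
    k <- which.min(r$lengths)          # shortest first; ties -> earliest
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    left_len <- if (k > 1L) r$lengths[k - 1L] else -1L
    right_len <- if (k < length(r$lengths)) r$lengths[k + 1L] else -1L
    new_val <- if (left_len >= right_len) r$values[k - 1L] else r$values[k + 1L]
    lab[starts[k]:ends[k]] <- new_val
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(
    segment = seq_along(r$lengths),
    kind = ifelse(r$values, "stable", "shifting"),
    start_s = si$time_s[starts],
    end_s = si$time_s[ends],
    stringsAsFactors = FALSE
  )
  out$duration_s <- out$end_s - out$start_s
  out$modal_offset <- NA_integer_
  for (i in seq_len(nrow(out))) {
    if (out$kind[i] == "stable")
      out$modal_offset[i] <- .modal_int(si$offset_sixteenths[starts[i]:ends[i]])
  }
  class(out) <- c("segment_list", "data.frame")
  out
}
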