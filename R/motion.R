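#' Parameters for motion-trace synthesis
#'
#' Defaults emulate the measurement rig of a seated piano duet: optical
#' head tracking at 120 Hz, the partner seated about 60 degrees off the
#' forward direction, chair-pressure sway in arbitrary units, and pupil
#' diameter with blink gaps.
#'
#' @param fs sampling rate of all traces, Hz.
#' @param head_amp_m amplitude of the beat-locked head oscillation, metres.
#' @param head_noise_sd SD of isotropic 3D head noise, as a fraction of
#'   `head_amp_m` (default 0.3).
#' @param partner_angle_deg azimuth of the partner from the test
#'   performer's forward direction, degrees.
#' @param partner_distance_m distance between the performers' heads.
#' @param gaze_noise_deg SD of angular gaze noise, degrees.
#' @param gaze_dwell_s duration of the transition-locked gaze reorientation
#'   toward the partner at each shifting-bar start.
#' @param sway_step_scale size of the posture step change (in sway SD
#'   units) injected at the middle scheduled transition.
#' @param blink_rate_hz Poisson rate of blink gaps in the pupil trace.
#' @param blink_range_ms blink gap duration range, ms.
#' @param nod_prob probability that a stable-bar start carries a head nod
#'   (per performer).
#' @return an object of class `motion_params`.
#' @export
motion_params <- function(fs = 120, head_amp_m = 0.02, head_noise_sd = 0.3,
                          partner_angle_deg = 60, partner_distance_m = 2,
                          gaze_noise_deg = 2, gaze_dwell_s = 2,
                          sway_step_scale = 2, blink_rate_hz = 0.25,
                          blink_range_ms = c(60, 200), nod_prob = 1) {
  stopifnot(fs > 0, head_amp_m >= 0, head_noise_sd >= 0,
            partner_distance_m > 0, gaze_dwell_s >= 0,
            blink_rate_hz >= 0, length(blink_range_ms) == 2L,
            nod_prob >= 0, nod_prob <= 1)
  structure(as.list(environment()), class = "motion_params")
}

# Continuous cycle phase of a stream on an arbitrary grid (radians).
.phase_on_grid <- function(stream, tt) {
  on <- stream$onsets_s
  ph <- 2 * pi * (seq_along(on) - 1L) / 12
  stats::approx(on, ph, xout = tt, rule = 2, ties = "ordered")$y
}

#' Synthesize motion, gaze, sway, pupil and nod traces for a duet
#'
#' Head position oscillates at the beat frequency (`tempo_bpm / 60` Hz,
#' 1.2 Hz at the default 72 BPM: the cycle phase advances one cycle per
#' two beats, and the head follows `sin(2 * phase)`), phase-locked to each
#' performer's own part, plus isotropic Gaussian noise. The test
#' performer's gaze points forward with transition-locked reorientations
#' toward the partner's head. Chair pressure is a slow bounded random walk
#' over 4 channels with one posture step change at the middle scheduled
#' transition. Pupil diameter carries Poisson-timed blink gaps (NA).
#'
#' @param perf a [simulate_duet()] performance.
#' @param seed integer seed (deterministic per-signal sub-streams).
#' @param params a [motion_params()].
#' @return an object of class `motion_traces`: list with `time_s`,
#'   `head_pos` (list `top`, `bottom`: n x 3 matrices, metres),
#'   `head_base` (list of base positions), `gaze_dir` (n x 3 unit rows,
#'   test performer), `sway_pressure` (n x 4), `pupil_mm`, `nods`
#'   (data frame `performer`, `time_s`), `fs`, `params`.
#' @export
synthesize_motion <- function(perf, seed = 1L, params = motion_params()) {
  stopifnot(inherits(perf, "duet_performance"),
            inherits(params, "motion_params"))
  fs <- params$fs
  t_end <- perf$schedule$end_s[nrow(perf$schedule)]
  tt <- seq(0, t_end, by = 1 / fs)
  n <- length(tt)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)

  ang <- params$partner_angle_deg * pi / 180
  base_top <- c(0, 0, 1.2)
  u_partner <- c(sin(ang), cos(ang), 0)          # forward is +y
  base_bottom <- base_top + params$partner_distance_m * u_partner

  mk_head <- function(stream, base, k) {
    set.seed(.substream_seed(seed, k))
    ph <- .phase_on_grid(stream, tt)
    osc <- params$head_amp_m * sin(2 * ph)
    noise <- matrix(stats::rnorm(3 * n, 0,
                                 params$head_noise_sd * params$head_amp_m),
                    ncol = 3)
    sweep(noise, 2, base, "+") + cbind(osc, 0, 0)
  }
  head_top <- mk_head(perf$streams$top, base_top, 11L)
  head_bottom <- mk_head(perf$streams$bottom, base_bottom, 12L)

  # gaze: forward, with a dwell toward the partner at each shifting-bar start
  set.seed(.substream_seed(seed, 13L))
  fwd <- c(0, 1, 0)
  w <- numeric(n)                                # 0 = forward, 1 = partner
  shifts <- perf$schedule$start_s[perf$schedule$kind == "shifting"]
  for (s in shifts) w[tt >= s & tt < s + params$gaze_dwell_s] <- 1
  gaze <- outer(1 - w, fwd) + outer(w, u_partner)
  gaze <- gaze + matrix(stats::rnorm(3 * n, 0,
                                     sin(params$gaze_noise_deg * pi / 180)),
                        ncol = 3)
  gaze <- gaze / sqrt(rowSums(gaze^2))

  # sway: 4-channel slow bounded walk + posture step at middle transition
  set.seed(.substream_seed(seed, 14L))
  smooth_walk <- function() {
    steps <- stats::rnorm(n, 0, 1 / sqrt(fs))
    wlk <- cumsum(steps)
    wlk <- abs((wlk + 3) %% 12 - 6) - 3          # reflect into [-3, 3]
    stats::filter(wlk, rep(1 / fs, fs), sides = 2L) |> as.numeric() |>
      (\(z) { z[is.na(z)] <- z[which(!is.na(z))[1]]; z })()
  }
  sway <- vapply(1:4, function(i) smooth_walk(), numeric(n))
  mid_shift <- shifts[ceiling(length(shifts) / 2)]
  step_vec <- params$sway_step_scale * c(1, -1, 1, -1) *
    stats::sd(sway[, 1])
  after <- tt >= mid_shift
  sway[after, ] <- sway[after, ] + rep(step_vec, each = sum(after))
  sway <- sway + 10                              # arbitrary-unit baseline

  # pupil: baseline + slow modulation + noise, with blink gaps
  set.seed(.substream_seed(seed, 15L))
  pupil <- 3.5 + 0.3 * sin(2 * pi * tt / 60) + stats::rnorm(n, 0, 0.02)
  n_blinks <- stats::rpois(1, params$blink_rate_hz * t_end)
  if (n_blinks > 0) {
    b_start <- sort(stats::runif(n_blinks, 0, t_end))
    b_dur <- stats::runif(n_blinks, params$blink_range_ms[1],
                          params$blink_range_ms[2]) / 1000
    for (b in seq_len(n_blinks))
      pupil[tt >= b_start[b] & tt < b_start[b] + b_dur[b]] <- NA_real_
  }

  # nods at (a configurable subset of) stable-bar starts
  set.seed(.substream_seed(seed, 16L))
  stable_starts <- perf$schedule$start_s[perf$schedule$kind == "stable"]
  nods <- do.call(rbind, lapply(c("top", "bottom"), function(p) {
    pick <- stats::runif(length(stable_starts)) <= params$nod_prob
    if (!any(pick)) return(NULL)
    data.frame(performer = p, time_s = stable_starts[pick],
               stringsAsFactors = FALSE)
  }))
  if (is.null(nods))
    nods <- data.frame(performer = character(0), time_s = numeric(0))
  nods <- nods[order(nods$time_s), , drop = FALSE]
  rownames(nods) <- NULL

  structure(list(time_s = tt,
                 head_pos = list(top = head_top, bottom = head_bottom),
                 head_base = list(top = base_top, bottom = base_bottom),
                 gaze_dir = gaze, sway_pressure = sway, pupil_mm = pupil,
                 nods = nods, fs = fs, params = params),
            class = "motion_traces")
}

#' Generate a standalone synthetic postural-sway series
#'
#' A bounded (reflected at +/- 3) Gaussian random walk, the minimal model
#' of slow seated weight displacement used for calibrating recurrence
#' radii and exercising the sway analytics without a full simulation.
#'
#' @param duration_s length of the series, seconds.
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return list with `time_s`, `sway` (arbitrary units), `fs`.
#' @export
synth_sway_series <- function(duration_s = 120, fs = 40, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- round(duration_s * fs)
  w <- cumsum(stats::rnorm(n, 0, 1 / sqrt(fs)))
  w <- abs((w + 3) %% 12 - 6) - 3
  list(time_s = (seq_len(n) - 1L) / fs, sway = w, fs = fs)
}
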