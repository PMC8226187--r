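#' Performer parameters for the duet simulator
#'
#' @param role one of `"timekeeper"` (top part, constant tempo),
#'   `"shifter"` (bottom part, accelerates during shifting bars) or
#'   `"agent"` (bottom part produced by the Kuramoto virtual partner).
#' @param timing_jitter_sd_ms SD of Gaussian per-onset timing jitter
#'   (truncated at 3 SD), milliseconds. Default 8 ms, a typical expert
#'   keystroke dispersion.
#' @param tempo_drift_sd BPM step SD of a reflected random walk (bounded to
#'   +/- 3 BPM) modelling slow tempo wander. Default 0.2.
#' @param latency_ms optional `c(mean, sd)` latency in ms added to the
#'   partner-visible copy of this performer's signals (a full-body
#'   motion-streaming chain typically measures around 54 +/- 11 ms);
#'   `NULL` = off.
#' @param phase_correction per-onset fraction of the observed asynchrony
#'   (accumulated plus current tempo deviation) a coupled performer
#'   corrects, as in linear phase-correction models of sensorimotor
#'   synchronization (shifter only). 1 (default) = full correction, so an
#'   expert duo's relative timing noise reduces to per-onset jitter;
#'   0 = the shifter's tempo drift accumulates uncorrected.
#' @param agent agent parameters from [agent_params()], used when
#'   `role = "agent"`.
#' @return an object of class `performer_params`.
#' @export
performer_params <- function(role = c("timekeeper", "shifter", "agent"),
                             timing_jitter_sd_ms = 8,
                             tempo_drift_sd = 0.2,
                             latency_ms = NULL,
                             phase_correction = 1,
                             agent = agent_params()) {
  role <- match.arg(role)
  if (!.is_num1(timing_jitter_sd_ms) || timing_jitter_sd_ms < 0)
    .stop_config("timing_jitter_sd_ms", "must be >= 0")
  if (!.is_num1(tempo_drift_sd) || tempo_drift_sd < 0)
    .stop_config("tempo_drift_sd", "must be >= 0")
  if (!is.null(latency_ms)) {
    if (!is.numeric(latency_ms) || length(latency_ms) != 2L ||
        any(latency_ms < 0))
      .stop_config("latency_ms", "must be NULL or c(mean, sd) in ms, >= 0")
  }
  if (!.is_num1(phase_correction) || phase_correction < 0 ||
      phase_correction > 1)
    .stop_config("phase_correction", "must lie in [0, 1]")
  structure(list(role = role,
                 timing_jitter_sd_ms = as.numeric(timing_jitter_sd_ms),
                 tempo_drift_sd = as.numeric(tempo_drift_sd),
                 latency_ms = latency_ms,
                 phase_correction = as.numeric(phase_correction),
                 agent = agent),
            class = "performer_params")
}

# Reflected random walk bounded to +/- bound, one step per onset.
.drift_walk <- function(n, sd, bound = 3) {
  if (n <= 0L) return(numeric(0))
  if (sd == 0) return(numeric(n))
  w <- cumsum(stats::rnorm(n, 0, sd))
  # reflect into [-bound, bound]
  w <- abs((w + bound) %% (4 * bound) - 2 * bound) - bound
  w
}

.truncated_jitter <- function(n, sd_s) {
  if (sd_s == 0 || n == 0L) return(numeric(n))
  pmin(pmax(stats::rnorm(n, 0, sd_s), -3 * sd_s), 3 * sd_s)
}

# Apply per-onset tempo drift to an ideal onset grid: each inter-onset
# interval is stretched by tempo0 / (tempo0 + w_k).
.apply_drift <- function(onsets, tempo0, w) {
  if (length(onsets) < 2L || !length(w) || all(w == 0)) return(onsets)
  ioi <- diff(onsets)
  onsets[1] + c(0, cumsum(ioi * tempo0 / (tempo0 + w[seq_along(ioi)])))
}

#' Simulate a duet performance of the phasing schedule
#'
#' The timekeeper (top part) emits isochronous sixteenth notes at the base
#' tempo; the shifter (bottom part) plays the same pattern but raises its
#' note rate during each shifting bar by exactly the amount needed to gain
#' one sixteenth note over the bar, holding the gained offset through the
#' following stable bar. Timing jitter (per onset) and tempo drift (random
#' walk) are then superimposed per performer. With `p2$role = "agent"` the
#' bottom part is produced by the closed-loop Kuramoto partner of
#' [step_agent()] tracking the (jittered) top part.
#'
#' @param score a [score_spec()].
#' @param p1 [performer_params()] for the top part (`role` must be
#'   `"timekeeper"`).
#' @param p2 [performer_params()] for the bottom part (`"shifter"` or
#'   `"agent"`).
#' @param seed integer seed; identical (config, seed) give identical output.
#' @return an object of class `duet_performance`: list with `streams`
#'   (named `top`, `bottom` [note_stream()]s), `schedule`
#'   ([generate_score()] output), `score`, `seed`.
#' @examples
#' perf <- simulate_duet(score_spec(), seed = 1)
#' length(perf$streams$top$onsets_s)
#' @export
simulate_duet <- function(score = score_spec(),
                          p1 = performer_params("timekeeper"),
                          p2 = performer_params("shifter"),
                          seed = 1L) {
  stopifnot(inherits(score, "score_spec"),
            inherits(p1, "performer_params"),
            inherits(p2, "performer_params"))
  if (p1$role != "timekeeper")
    .stop_config("p1$role", "must be 'timekeeper'")
  if (!p2$role %in% c("shifter", "agent"))
    .stop_config("p2$role", "must be 'shifter' or 'agent'")
  schedule <- generate_score(score)
  six <- sixteenth_duration(score$tempo_bpm, score$sixteenths_per_beat)
  t_end <- schedule$end_s[nrow(schedule)]

  # --- top part: isochronous grid, drifted, then jittered ---
  # (two spare grid points past the schedule end support warping the
  # final bar boundary below; they are dropped from the emitted stream)
  n1 <- floor(t_end / six - 1e-9)
  ideal1 <- (0:(n1 + 2L)) * six
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream_seed(seed, 1L))
  w1 <- .drift_walk(length(ideal1) - 1L, p1$tempo_drift_sd)
  on1d <- .apply_drift(ideal1, score$tempo_bpm, w1)
  set.seed(.substream_seed(seed, 2L))
  on1 <- on1d[1:(n1 + 1L)] +
    .truncated_jitter(n1 + 1L, p1$timing_jitter_sd_ms / 1000)
  on1 <- .force_increasing(pmax(on1, 0))
  top <- note_stream(on1,
                     pitches = score$pattern_pitches[(0:n1) %% 12 + 1L],
                     velocities = 80L, performer_id = "top")

  if (p2$role == "agent") {
    bottom <- .agent_bottom_part(top, score, schedule, p2, seed)
  } else {
    # --- bottom part, coupled to the timekeeper's realized beat ---
    # The shifter derives its timing from the partner's (drifted,
    # pre-jitter) sixteenth grid plus the scheduled offset: tempo drift is
    # common-mode for a duo playing together. Its target count is
    # u2(t) = u1(t) + offset(t), piecewise linear with nodes at the
    # partner's grid points and the (warped) bar boundaries; onsets fall
    # where u2 crosses integers.
    bounds <- c(schedule$start_s, t_end)
    bounds_real <- stats::approx(ideal1, on1d, xout = bounds,
                                 ties = "ordered")$y
    nodes <- sort(unique(c(on1d, bounds_real)))
    u1 <- stats::approx(on1d, seq_along(on1d) - 1L, xout = nodes,
                        ties = "ordered")$y
    off_nominal <- stats::approx(bounds_real, .offset_at(schedule, bounds),
                                 xout = nodes, rule = 2,
                                 ties = "ordered")$y
    u2 <- u1 + off_nominal
    n2 <- floor(max(u2) - 1e-9)
    ideal2 <- stats::approx(u2, nodes, xout = 0:n2, ties = "ordered")$y
    # residual shifter tempo deviations, leaky-integrated: a coupled
    # performer corrects a fraction of its accumulated asynchrony per note
    set.seed(.substream_seed(seed, 3L))
    w2 <- .drift_walk(n2, p2$tempo_drift_sd)
    if (p2$tempo_drift_sd > 0 && p2$phase_correction < 1) {
      delta <- diff(ideal2) *
        (score$tempo_bpm / (score$tempo_bpm + w2[seq_len(n2)]) - 1)
      a <- numeric(n2 + 1L)
      for (k in seq_len(n2))
        a[k + 1L] <- (1 - p2$phase_correction) * (a[k] + delta[k])
      on2 <- ideal2 + a
    } else on2 <- ideal2
    set.seed(.substream_seed(seed, 4L))
    on2 <- on2 + .truncated_jitter(length(on2), p2$timing_jitter_sd_ms / 1000)
    on2 <- .force_increasing(pmax(on2, 0))
    bottom <- note_stream(on2,
                          pitches = score$pattern_pitches[(0:n2) %% 12 + 1L],
                          velocities = 80L, performer_id = "bottom")
  }

  structure(list(streams = list(top = top, bottom = bottom),
                 schedule = schedule, score = score,
                 seed = as.integer(seed)),
            class = "duet_performance")
}

.force_increasing <- function(x, eps = 1e-6) {
  if (length(x) < 2L) return(x)
  for (i in 2:length(x)) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + eps
  x
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.duet_performance <- function(x, ...) {
  cat(sprintf("<duet_performance: seed %d, %d bars, top %d / bottom %d onsets>\n",
              x$seed, nrow(x$schedule), length(x$streams$top$onsets_s),
              length(x$streams$bottom$onsets_s)))
  invisible(x)
}
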