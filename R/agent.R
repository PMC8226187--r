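#' Convert between tempo (BPM) and cycle frequency (rad/s)
#'
#' One cycle is one 12-note pattern; at `bpm` beats per minute with
#' `sixteenths_per_beat` sixteenths to the beat the pattern repeats at
#' `bpm * sixteenths_per_beat / (60 * 12)` Hz.
#'
#' @param bpm tempo in beats per minute.
#' @param omega cycle frequency in rad/s.
#' @param sixteenths_per_beat sixteenths per beat (default 6).
#' @return `bpm_to_omega()` returns rad/s; `omega_to_bpm()` returns BPM.
#' @export
bpm_to_omega <- function(bpm, sixteenths_per_beat = 6L) {
  2 * pi * bpm * sixteenths_per_beat / (60 * 12)
}

#' @rdname bpm_to_omega
#' @export
omega_to_bpm <- function(omega, sixteenths_per_beat = 6L) {
  omega * 60 * 12 / (2 * pi * sixteenths_per_beat)
}

#' Parameters of the Kuramoto virtual partner
#'
#' The agent is a single phase oscillator with phase `theta` and frequency
#' `omega`, coupled to the live performer's estimated cycle phase and
#' attracted toward a natural tempo (72 BPM by default):
#' \deqn{\dot\theta = \omega + K \sin(\theta_{live} + \Delta - \theta)}
#' \deqn{\dot\omega = \gamma(\omega_0 - \omega) + K_f \sin(\theta_{live} + \Delta - \theta)}
#' where `Delta` is the scheduled target offset in radians.
#'
#' @param K phase coupling gain, rad/s (>= 0).
#' @param gamma frequency relaxation rate toward the attractor, 1/s.
#' @param K_f frequency coupling gain, rad/s^2; default `K / 10`; 0 gives
#'   phase-only coupling.
#' @param natural_bpm attractor tempo in BPM.
#' @param dt integration step in seconds (explicit Euler), must be <= 0.05.
#' @param ioi_window number of recent inter-onset intervals whose median
#'   sets the live-phase extrapolation rate (responsiveness knob).
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(K = 0.5, gamma = 0.05, K_f = K / 10,
                         natural_bpm = 72, dt = 0.01, ioi_window = 12L) {
  if (!.is_num1(K) || K < 0) .stop_config("K", "must be >= 0")
  if (!.is_num1(gamma) || gamma < 0) .stop_config("gamma", "must be >= 0")
  if (!.is_num1(K_f) || K_f < 0) .stop_config("K_f", "must be >= 0")
  if (!.is_num1(natural_bpm) || natural_bpm <= 0)
    .stop_config("natural_bpm", "must be > 0")
  if (!.is_num1(dt) || dt <= 0 || dt > 0.05)
    .stop_config("dt", "must lie in (0, 0.05]")
  structure(list(K = K, gamma = gamma, K_f = K_f, natural_bpm = natural_bpm,
                 dt = dt, ioi_window = as.integer(ioi_window)),
            class = "agent_params")
}

#' Agent oscillator state
#'
#' @param theta unwrapped cycle phase, radians.
#' @param omega cycle frequency, rad/s.
#' @param params an [agent_params()].
#' @param target_offset scheduled relative phase in radians (agent ahead of
#'   live performer).
#' @return an object of class `agent_state`.
#' @export
agent_state <- function(theta = 0, omega = bpm_to_omega(72),
                        params = agent_params(), target_offset = 0) {
  structure(list(theta = theta, omega = omega, params = params,
                 target_offset = target_offset),
            class = "agent_state")
}

#' Track the live performer's cycle phase from note onsets
#'
#' Phase equals `2*pi*k/12` at the (k+1)-th onset (k = 0, 1, ...) and is
#' extrapolated linearly after the most recent onset at rate
#' `2*pi / (12 * median of the last `ioi_window` IOIs)`, capped at one
#' sixteenth (`2*pi/12`) so the estimate never overtakes the next onset's
#' phase and is non-decreasing in `t`.
#'
#' @param onsets a [note_stream()] or numeric onset times (s).
#' @param t query time in seconds (scalar or vector).
#' @param ioi_window IOI median window (default 12).
#' @return list with `theta_live` (radians, same length as `t`),
#'   `last_onset_s`, `onset_index` (1-based index of the most recent onset).
#' @export
track_live_phase <- function(onsets, t, ioi_window = 12L) {
  if (inherits(onsets, "note_stream")) onsets <- onsets$onsets_s
  tl <- .live_phase_fun(onsets, ioi_window)
  idx <- findInterval(t, onsets)
  if (any(idx < 2L))
    stop("insufficient data: need at least 2 onsets before t", call. = FALSE)
  list(theta_live = tl(t), last_onset_s = onsets[idx],
       onset_index = idx)
}

# Vectorized causal phase estimator over a fixed onset vector.
.live_phase_fun <- function(onsets, ioi_window = 12L) {
  n <- length(onsets)
  if (n < 2L)
    stop("insufficient data: need at least 2 onsets", call. = FALSE)
  ioi <- diff(onsets)
  med <- numeric(n)
  for (k in seq_len(n)) {
    if (k == 1L) { med[k] <- ioi[1] ; next }
    lo <- max(1L, k - ioi_window)
    med[k] <- stats::median(ioi[lo:(k - 1L)])
  }
  rate <- 2 * pi / (12 * med)
  step <- 2 * pi / 12
  function(t) {
    idx <- pmax(findInterval(t, onsets), 1L)
    base <- (idx - 1L) * step
    base + pmin(pmax(t - onsets[idx], 0) * rate[idx], step)
  }
}

#' Advance the agent one Euler step
#'
#' @param state an [agent_state()].
#' @param live either the list returned by [track_live_phase()] (its
#'   `theta_live` is used) or `NULL` for free run (no phase coupling term).
#' @param dt step size in seconds, in (0, 0.05].
#' @return the updated `agent_state`.
#' @export
step_agent <- function(state, live = NULL, dt = state$params$dt) {
  stopifnot(inherits(state, "agent_state"))
  if (!.is_num1(dt) || dt <= 0 || dt > 0.05)
    stop("step-size error: dt must lie in (0, 0.05]", call. = FALSE)
  p <- state$params
  omega0 <- bpm_to_omega(p$natural_bpm)
  err <- if (is.null(live)) 0 else
    sin(live$theta_live + state$target_offset - state$theta)
  state$theta <- state$theta + state$omega * dt + p$K * err * dt
  state$omega <- state$omega + p$gamma * (omega0 - state$omega) * dt +
    p$K_f * err * dt
  state
}

#' Run the agent over a time span
#'
#' Integrates the oscillator with explicit Euler steps, optionally coupled
#' to a live onset stream and a target-offset schedule.
#'
#' @param state initial [agent_state()].
#' @param duration_s total integration time, seconds.
#' @param live_onsets optional [note_stream()] / numeric onsets to track.
#' @param schedule optional [generate_score()] schedule supplying the
#'   time-varying target offset (linear ramp across shifting bars).
#' @param dt Euler step (default from params).
#' @return list with vectors `time_s`, `theta`, `omega`, and `state` (final).
#' @export
run_agent <- function(state, duration_s, live_onsets = NULL,
                      schedule = NULL, dt = state$params$dt) {
  p <- state$params
  nstep <- ceiling(duration_s / dt)
  tgrid <- (0:nstep) * dt
  omega0 <- bpm_to_omega(p$natural_bpm)
  theta_live <- NULL
  if (!is.null(live_onsets)) {
    if (inherits(live_onsets, "note_stream")) live_onsets <- live_onsets$onsets_s
    tl <- .live_phase_fun(live_onsets, p$ioi_window)
    theta_live <- tl(tgrid)
  }
  target <- if (is.null(schedule)) rep(state$target_offset, nstep + 1L) else
    2 * pi / 12 * .offset_at(schedule, tgrid)
  theta <- omega <- numeric(nstep + 1L)
  theta[1] <- state$theta; omega[1] <- state$omega
  for (i in seq_len(nstep)) {
    err <- if (is.null(theta_live)) 0 else
      sin(theta_live[i] + target[i] - theta[i])
    theta[i + 1L] <- theta[i] + omega[i] * dt + p$K * err * dt
    omega[i + 1L] <- omega[i] + p$gamma * (omega0 - omega[i]) * dt +
      p$K_f * err * dt
  }
  state$theta <- theta[nstep + 1L]
  state$omega <- omega[nstep + 1L]
  state$target_offset <- target[nstep + 1L]
  list(time_s = tgrid, theta = theta, omega = omega, state = state)
}

#' Render a prerecorded part through the agent's phase trajectory
#'
#' Emits the k-th prerecorded note at the wall time when the agent phase
#' crosses `2*pi*(k-1)/12`, i.e. time-warps the prerecorded performance so
#' its cycle phase follows the agent's. The returned warp map (prerecorded
#' time to wall time at the note onsets) can retime accompanying motion
#' traces.
#'
#' @param trajectory list with `time_s` and `theta` from [run_agent()].
#' @param prerecorded a [note_stream()] (the bottom part to be replayed).
#' @return list with `stream` (a [note_stream()]) and `warp` (data frame
#'   `t_pre`, `t_wall`).
#' @export
render_agent_stream <- function(trajectory, prerecorded) {
  stopifnot(inherits(prerecorded, "note_stream"))
  th <- trajectory$theta
  if (any(diff(th) <= 0))
    stop("controller instability: agent phase is not strictly increasing",
         call. = FALSE)
  n_pre <- length(prerecorded$onsets_s)
  targets <- 2 * pi / 12 * (seq_len(n_pre) - 1L)
  keep <- targets >= th[1] & targets <= th[length(th)]
  t_wall <- stats::approx(th, trajectory$time_s, xout = targets[keep],
                          ties = "ordered")$y
  stream <- note_stream(t_wall,
                        pitches = prerecorded$pitches[keep],
                        velocities = prerecorded$velocities[keep],
                        performer_id = prerecorded$performer_id)
  list(stream = stream,
       warp = data.frame(t_pre = prerecorded$onsets_s[keep],
                         t_wall = t_wall))
}

# Closed-loop bottom part for simulate_duet(role = "agent"): the agent
# tracks the (already jittered) top part, follows the schedule's offset
# ramp, and replays an ideal isochronous prerecording of the pattern.
.agent_bottom_part <- function(top, score, schedule, p2, seed) {
  t_end <- schedule$end_s[nrow(schedule)]
  st <- agent_state(theta = 0, omega = bpm_to_omega(score$tempo_bpm),
                    params = p2$agent)
  live <- top$onsets_s
  if (!is.null(p2$latency_ms)) {
    # the agent hears the live part through the streaming chain
    old_l <- .Random.seed_save()
    set.seed(.substream_seed(seed, 6L))
    live <- sort(live + stats::rnorm(length(live), p2$latency_ms[1] / 1000,
                                     p2$latency_ms[2] / 1000))
    .Random.seed_restore(old_l)
  }
  traj <- run_agent(st, t_end, live_onsets = live, schedule = schedule)
  six <- sixteenth_duration(score$tempo_bpm, score$sixteenths_per_beat)
  n_pre <- floor(max(traj$theta) / (2 * pi / 12)) + 1L
  pre <- note_stream((seq_len(n_pre) - 1L) * six,
                     pitches = score$pattern_pitches[(seq_len(n_pre) - 1L) %% 12 + 1L],
                     velocities = 80L, performer_id = "bottom")
  out <- render_agent_stream(traj, pre)$stream
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream_seed(seed, 5L))
  on <- out$onsets_s +
    .truncated_jitter(length(out$onsets_s), p2$timing_jitter_sd_ms / 1000)
  note_stream(.force_increasing(pmax(on, 0)), pitches = out$pitches,
              velocities = out$velocities, performer_id = "bottom")
}
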