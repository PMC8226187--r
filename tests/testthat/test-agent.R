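test_that("live phase tracking matches the onset-count convention", {
  ioi <- 60 / (72 * 6)
  on <- (0:48) * ioi
  # at onset index 25 (k = 24) the phase is 24 * 2pi/12 = 4pi
  est <- track_live_phase(on, on[25])
  expect_equal(est$theta_live, 4 * pi, tolerance = 1e-12)
  # midway between onsets the phase has advanced half a sixteenth
  est2 <- track_live_phase(on, on[25] + ioi / 2)
  expect_equal(est2$theta_live, 4 * pi + pi / 12, tolerance = 1e-9)
  expect_error(track_live_phase(on, on[1]), "insufficient")
})

test_that("tracked phase is non-decreasing for jittered onsets", {
  perf <- simulate_duet(small_score(), seed = 5)
  on <- perf$streams$top$onsets_s
  tt <- seq(on[3], max(on), by = 0.005)
  th <- track_live_phase(on, tt)$theta_live
  expect_true(all(diff(th) >= -1e-12))
})

test_that("free-running agent converges to the 72 BPM attractor", {
  # from anywhere in [50, 100] BPM, |tempo - 72| < 0.1 BPM after 5/gamma
  for (bpm0 in c(50, 80, 100)) {
    st <- agent_state(omega = bpm_to_omega(bpm0),
                      params = agent_params(K = 0))
    tr <- run_agent(st, 6 / 0.05)   # t > 5/gamma
    expect_lt(abs(omega_to_bpm(tr$state$omega) - 72), 0.1)
  }
})

test_that("the phase-locked equilibrium is a fixed point of the step map", {
  p <- agent_params()
  live <- list(theta_live = 10)
  st <- agent_state(theta = 10 + 0.3, omega = bpm_to_omega(72),
                    params = p, target_offset = 0.3)
  st2 <- step_agent(st, live, dt = 0.01)
  # phase error stays zero; phase advances by omega*dt exactly
  expect_equal(st2$theta - st$theta, st$omega * 0.01, tolerance = 1e-12)
  expect_equal(st2$omega, st$omega, tolerance = 1e-12)
  expect_error(step_agent(st, live, dt = 0), "step-size")
  expect_error(step_agent(st, live, dt = 0.1), "step-size")
})

test_that("locking error matches the Kuramoto closed form below the locking threshold", {
  # defaults: steady omega = (gamma*omega0 + (K_f/K)*omega_live)/(gamma + K_f/K),
  # residual mismatch gives error arcsin(d_omega/K)
  on <- seq(0, 150, by = 60 / (74 * 6))
  st <- agent_state(omega = bpm_to_omega(74), params = agent_params())
  tr <- run_agent(st, 140, live_onsets = on)
  sel <- tr$time_s > 100 & tr$time_s < 139
  live_phase <- track_live_phase(on, tr$time_s[sel])$theta_live
  err <- tr$theta[sel] - live_phase
  p <- agent_params()
  omega_ss <- (p$gamma * bpm_to_omega(72) + (p$K_f / p$K) * bpm_to_omega(74)) /
    (p$gamma + p$K_f / p$K)
  expected <- asin((bpm_to_omega(74) - omega_ss) / p$K)
  expect_lt(abs(mean(err)) , 2 * pi / 24)
  expect_equal(abs(mean(err)), expected, tolerance = 0.05)
})

test_that("phase error converges when mismatch < K and drifts when > K", {
  # pure phase coupling: gamma = 0 (attractor at the live tempo), K_f = 0
  lock_err <- function(live_bpm, K) {
    on <- seq(0, 80, by = 60 / (live_bpm * 6))
    st <- agent_state(omega = bpm_to_omega(72),
                      params = agent_params(K = K, gamma = 0, K_f = 0,
                                            natural_bpm = 72))
    tr <- run_agent(st, 75, live_onsets = on)
    sel <- tr$time_s > 50
    tr$theta[sel] - track_live_phase(on, tr$time_s[sel])$theta_live
  }
  # mismatch 4 BPM = 0.21 rad/s < K = 0.5: wrapped error settles
  e_lock <- lock_err(76, 0.5)
  expect_lt(stats::sd(tail(e_lock, 500)), 1e-3)
  # mismatch 20 BPM = 1.05 rad/s > K = 0.5: error keeps drifting
  e_drift <- lock_err(92, 0.5)
  expect_gt(abs(e_drift[length(e_drift)] - e_drift[1]), 2 * pi)
})

test_that("Euler integration is stable under step halving", {
  on <- seq(0, 60, by = 60 / (73 * 6))
  run_end <- function(dt) {
    st <- agent_state(omega = bpm_to_omega(72),
                      params = agent_params(dt = dt))
    run_agent(st, 50, live_onsets = on, dt = dt)$state$theta
  }
  expect_lt(abs(run_end(0.01) - run_end(0.005)), 1e-3)
})

test_that("rendering through the identity and a 2x phase map warps onsets as expected", {
  pre <- iso_stream(60, id = "pre")
  tt <- seq(0, 10, by = 0.01)
  omega <- bpm_to_omega(72)
  ident <- list(time_s = tt, theta = omega * tt)
  out <- render_agent_stream(ident, pre)
  keep <- pre$onsets_s <= 10
  expect_equal(out$stream$onsets_s, pre$onsets_s[keep], tolerance = 1e-9)
  expect_equal(out$stream$pitches, pre$pitches[keep])
  double <- list(time_s = tt, theta = 2 * omega * tt)
  out2 <- render_agent_stream(double, pre)
  expect_equal(diff(out2$stream$onsets_s),
               rep(60 / (72 * 6) / 2, length(out2$stream$onsets_s) - 1L),
               tolerance = 1e-9)
  expect_true(all(diff(out2$warp$t_wall) > 0))
  bad <- list(time_s = tt, theta = c(0, 1, 0.5, seq(2, length.out = length(tt) - 3)))
  expect_error(render_agent_stream(bad, pre), "instability")
})

test_that("closed-loop agent follows the scheduled offset ramp at stable-bar midpoints", {
  perf <- simulate_duet(score_spec(n_relations = 3L), tk0(),
                        performer_params("agent", timing_jitter_sd_ms = 0),
                        seed = 2)
  rel <- relative_phase(cycle_phase(perf$streams$top),
                        cycle_phase(perf$streams$bottom))
  sched <- perf$schedule
  mids <- (sched$start_s + sched$end_s)[sched$kind == "stable"] / 2
  idx <- findInterval(mids, rel$time_s)
  lead <- rel$dphi_unwrapped[idx]
  target <- 2 * pi / 12 * sched$target_offset_sixteenths[sched$kind == "stable"]
  expect_true(all(abs(lead - target) < 2 * pi / 24))
})
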