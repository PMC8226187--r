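test_that("default schedule has 25 alternating bars with the written durations", {
  sched <- generate_score(score_spec())
  expect_equal(nrow(sched), 25L)
  expect_equal(sum(sched$kind == "stable"), 13L)
  expect_equal(sum(sched$kind == "shifting"), 12L)
  expect_equal(sched$kind, rep(c("stable", "shifting"), length.out = 25L))
  # stable bar: 8 repetitions x 12 notes x one sixteenth at 72 BPM
  expect_equal(sched$end_s[1] - sched$start_s[1], 8 * 12 * 60 / (72 * 6))
  expect_equal(sched$end_s[2] - sched$start_s[2], 10)
  # offsets ascend 0..12 across stable bars
  expect_equal(sched$target_offset_sixteenths[sched$kind == "stable"], 0:12)
  # schedule conservation: bar durations tile the performance
  expect_equal(sched$start_s[-1], sched$end_s[-25])
  expect_equal(sched$start_s[1], 0)
})

test_that("minimal and invalid configurations are handled", {
  expect_equal(nrow(generate_score(score_spec(n_relations = 1L))), 3L)
  expect_error(score_spec(tempo_bpm = -1), "tempo_bpm")
  expect_error(score_spec(shift_duration_s = 0), "shift_duration_s")
  expect_error(score_spec(pattern_pitches = 1:5), "pattern_pitches")
  expect_error(performer_params(timing_jitter_sd_ms = -1),
               "timing_jitter_sd_ms")
})

test_that("noiseless timekeeper is isochronous and stable bars hold 96 onsets", {
  perf <- simulate_duet(score_spec(), tk0(), sh0(), seed = 1)
  ioi <- diff(perf$streams$top$onsets_s)
  expect_equal(ioi, rep(60 / (72 * 6), length(ioi)), tolerance = 1e-12)
  sched <- perf$schedule
  for (i in which(sched$kind == "stable")) {
    n_in_bar <- sum(perf$streams$top$onsets_s >= sched$start_s[i] - 1e-9 &
                      perf$streams$top$onsets_s < sched$end_s[i] - 1e-9)
    expect_equal(n_in_bar, 96L)
  }
})

test_that("noiseless shifter leads by k sixteenths in stable bar k and gains 2pi/12 per shift", {
  perf <- simulate_duet(score_spec(), tk0(), sh0(), seed = 1)
  ph1 <- cycle_phase(perf$streams$top)
  ph2 <- cycle_phase(perf$streams$bottom)
  rel <- relative_phase(ph1, ph2)
  sched <- perf$schedule
  mids <- (sched$start_s + sched$end_s) / 2
  idx <- findInterval(mids[sched$kind == "stable"], rel$time_s)
  lead <- rel$dphi_unwrapped[idx] / (2 * pi / 12)
  expect_equal(lead, 0:12, tolerance = 1e-6)
  # phase gain across each shifting bar is exactly one sixteenth
  phi_at <- function(stream, t)
    stats::approx(stream$onsets_s,
                  2 * pi * (seq_along(stream$onsets_s) - 1) / 12,
                  xout = t, rule = 2, ties = "ordered")$y
  dphi_at <- function(t)
    phi_at(perf$streams$bottom, t) - phi_at(perf$streams$top, t)
  for (i in which(sched$kind == "shifting")) {
    gain <- dphi_at(sched$end_s[i]) - dphi_at(sched$start_s[i])
    expect_equal(gain, 2 * pi / 12, tolerance = 1e-9)
  }
})

test_that("simulation is byte-identical under a repeated seed", {
  a <- simulate_duet(score_spec(), seed = 11)
  b <- simulate_duet(score_spec(), seed = 11)
  expect_identical(a, b)
  ta <- synthesize_motion(a, seed = 11)
  tb <- synthesize_motion(b, seed = 11)
  expect_identical(ta, tb)
  expect_false(identical(a, simulate_duet(score_spec(), seed = 12)))
})

test_that("noiseless head motion is a pure 1.2 Hz sinusoid on PC1", {
  perf <- simulate_duet(small_score(), tk0(), sh0(), seed = 1)
  par0 <- motion_params(head_noise_sd = 0, gaze_noise_deg = 0)
  tr <- synthesize_motion(perf, seed = 1, params = par0)
  pc <- head_pc1(tr$head_pos$top, fs = tr$fs)
  # dominant-axis series equals the oscillation up to normalization
  osc <- sin(2 * 2 * pi * 72 * 6 / (60 * 12) * tr$time_s)
  expect_gt(abs(stats::cor(pc$series, osc)), 0.999)
  # spectral check: beat frequency = tempo/60 = 1.2 Hz
  sp <- stats::spec.pgram(stats::ts(pc$series, frequency = tr$fs),
                          plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 1.2, tolerance = 0.02)
})

test_that("gaze pointed at the partner yields zero downstream angle", {
  perf <- simulate_duet(small_score(), tk0(), sh0(), seed = 1)
  tr <- synthesize_motion(perf, seed = 1,
                          params = motion_params(head_noise_sd = 0,
                                                 gaze_noise_deg = 0))
  u <- tr$head_base$bottom - tr$head_base$top
  gz <- matrix(u / sqrt(sum(u^2)), nrow = length(tr$time_s), ncol = 3,
               byrow = TRUE)
  ga <- gaze_angle(gz, tr$head_base$top, tr$head_base$bottom)
  expect_equal(max(ga$angle_deg), 0, tolerance = 1e-6)
})

test_that("generated signals are finite, blink gaps bounded, nods at stable-bar starts", {
  perf <- simulate_duet(small_score(), seed = 3)
  tr <- synthesize_motion(perf, seed = 3)
  expect_true(all(is.finite(tr$head_pos$top)))
  expect_true(all(is.finite(tr$sway_pressure)))
  expect_true(all(abs(sqrt(rowSums(tr$gaze_dir^2)) - 1) < 1e-12))
  # pupil gaps never exceed the configured blink maximum
  gap <- rle(is.na(tr$pupil_mm))
  if (any(gap$values))
    expect_lte(max(gap$lengths[gap$values]) / tr$fs,
               motion_params()$blink_range_ms[2] / 1000 + 2 / tr$fs)
  starts <- perf$schedule$start_s[perf$schedule$kind == "stable"]
  expect_true(all(vapply(tr$nods$time_s,
                         function(t) min(abs(starts - t)) < 1e-9,
                         logical(1))))
})

test_that("export round-trips MIDI within one tick and motion tables losslessly", {
  out <- withr::local_tempdir()
  perf <- simulate_duet(small_score(), seed = 4)
  tr <- synthesize_motion(perf, seed = 4)
  files <- export_performance(perf, tr, out)
  back <- parse_midi(files[["top_midi"]])
  expect_equal(length(back$onsets_s), length(perf$streams$top$onsets_s))
  # one tick at 480 ticks/quarter, 108 quarter-notes/min
  expect_lt(max(abs(back$onsets_s - perf$streams$top$onsets_s)),
            60 / (108 * 480))
  expect_equal(back$pitches, perf$streams$top$pitches)
  hd <- read_motion_tsv(files[["head_tsv"]])
  expect_equal(hd$top_x, tr$head_pos$top[, 1], tolerance = 1e-9)
  man <- jsonlite::read_json(files[["manifest"]], simplifyVector = TRUE)
  expect_equal(man$seed, 4L)
  expect_equal(man$score$tempo_bpm, 72)
})

test_that("synthetic sway generator is a bounded deterministic walk", {
  a <- synth_sway_series(30, 40, 1)
  b <- synth_sway_series(30, 40, 1)
  expect_identical(a, b)
  expect_true(all(abs(a$sway) <= 3))
  expect_equal(length(a$sway), 1200L)
})
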