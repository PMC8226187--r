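test_that("tempo and IOI statistics follow the dotted-quarter convention", {
  st <- iso_stream(100, ioi = 0.1388889)
  out <- tempo_and_ioi(st)
  expect_equal(out$tempo_mean_bpm, 72, tolerance = 1e-4)
  expect_equal(out$tempo_median_ioi_bpm, 72, tolerance = 1e-4)
  expect_equal(out$ioi_variability_ms, 0, tolerance = 1e-9)
  # alternating 130/150 ms: sample SD = 10.0336/ sqrt etc. computed directly
  on <- cumsum(c(0, rep(c(0.130, 0.150), 10)))
  alt <- tempo_and_ioi(note_stream(on))
  expect_equal(alt$ioi_variability_ms, stats::sd(rep(c(130, 150), 10)),
               tolerance = 1e-9)
  expect_equal(alt$ioi_variability_ms, 10.2598, tolerance = 1e-4)
  expect_error(tempo_and_ioi(iso_stream(5)), "insufficient")
})

test_that("cycle phase advances 2pi per 12 onsets and interpolates linearly", {
  st <- iso_stream(25)
  ph <- cycle_phase(st, fs = 72 * 6 / 60)  # grid hits the onsets exactly
  i12 <- which.min(abs(ph$time_s - st$onsets_s[13]))
  expect_equal(ph$phase_rad[i12], 2 * pi, tolerance = 1e-9)
  # halfway between onsets 0 and 1
  fine <- cycle_phase(st, fs = 2 / st$onsets_s[2])
  mid <- which.min(abs(fine$time_s - st$onsets_s[2] / 2))
  expect_equal(fine$phase_rad[mid], pi / 12, tolerance = 1e-9)
  expect_error(cycle_phase(note_stream(1)), "insufficient")
})

test_that("cycle phase is non-decreasing on jittered data and exact at onsets", {
  perf <- simulate_duet(small_score(), seed = 6)
  ph <- cycle_phase(perf$streams$top)
  expect_true(all(diff(ph$phase_rad) >= -1e-12))
  # noiseless: schedule-analytic phase at onset times
  perf0 <- simulate_duet(small_score(), tk0(), sh0(), seed = 1)
  on <- perf0$streams$top$onsets_s
  ph0 <- cycle_phase(perf0$streams$top, fs = 72 * 6 / 60)
  inside <- on >= ph0$time_s[1] & on <= ph0$time_s[length(ph0$time_s)]
  at_onsets <- stats::approx(ph0$time_s, ph0$phase_rad, xout = on[inside],
                             ties = "ordered")$y
  expect_equal(at_onsets, 2 * pi * (which(inside) - 1) / 12,
               tolerance = 1e-6)
})

test_that("relative phase handles identity, a one-onset shift, and disjoint supports", {
  st <- iso_stream(200)
  ph <- cycle_phase(st)
  rel0 <- relative_phase(ph, ph)
  expect_true(all(abs(rel0$dphi_wrapped) < 1e-12))
  expect_true(all(rel0$offset_sixteenths == 0L))
  ioi <- st$onsets_s[2]
  lead <- note_stream(st$onsets_s - ioi, performer_id = "lead")
  rel1 <- relative_phase(cycle_phase(st), cycle_phase(lead))
  interior <- rel1$time_s > st$onsets_s[3] &
    rel1$time_s < st$onsets_s[197]
  expect_equal(rel1$dphi_wrapped[interior],
               rep(2 * pi / 12, sum(interior)), tolerance = 1e-9)
  expect_true(all(rel1$offset_sixteenths[interior] == 1L))
  late <- note_stream(st$onsets_s + 100)
  expect_error(relative_phase(cycle_phase(st), cycle_phase(late)),
               "alignment")
})

test_that("synchronization index is 1 for constant, 0 for uniform, sinc for drift", {
  st <- iso_stream(2000)
  rel <- relative_phase(cycle_phase(st), cycle_phase(st))
  si <- synchronization_index(rel)
  expect_true(all(abs(si$si - 1) < 1e-12))
  # uniform angles over the window cancel
  n <- 400
  tu <- (0:(n - 1)) / 20
  relu <- structure(list(time_s = tu,
                         dphi_wrapped = (2 * pi * tu) %% (2 * pi),
                         dphi_unwrapped = 2 * pi * tu,
                         offset_sixteenths = integer(n), fs = 20),
                    class = "rel_phase_series")
  # linear drift of one full turn per window: resultant ~ 0
  siu <- synchronization_index(relu, window_s = 1, hop_s = 0.05)
  interior <- siu$time_s > 1 & siu$time_s < max(siu$time_s) - 1
  expect_true(all(siu$si[interior] < 0.06))
  # drift of Delta = 2pi/12 over the window: closed form |sinc(Delta/2)|
  drift_rate <- (2 * pi / 12) / 10
  reld <- structure(list(time_s = (0:4000) / 20,
                         dphi_wrapped = ((0:4000) / 20 * drift_rate) %% (2 * pi),
                         dphi_unwrapped = (0:4000) / 20 * drift_rate,
                         offset_sixteenths = integer(4001), fs = 20),
                    class = "rel_phase_series")
  sid <- synchronization_index(reld, window_s = 10)
  interior <- sid$time_s > 10 & sid$time_s < 190
  delta <- 2 * pi / 12
  expect_equal(mean(sid$si[interior]), sin(delta / 2) / (delta / 2),
               tolerance = 3e-4)   # discrete window vs continuous integral
  expect_error(synchronization_index(rel, window_s = 0.1), "window")
})

test_that("SI is invariant under a constant rotation of the relative phase", {
  perf <- simulate_duet(small_score(), seed = 8)
  rel <- relative_phase(cycle_phase(perf$streams$top),
                        cycle_phase(perf$streams$bottom))
  si1 <- synchronization_index(rel)
  rel2 <- rel
  rel2$dphi_wrapped <- (rel$dphi_wrapped + 1.23) %% (2 * pi)
  si2 <- synchronization_index(rel2)
  expect_equal(si1$si, si2$si, tolerance = 1e-12)
  expect_true(all(si1$si >= 0 & si1$si <= 1))
})

test_that("noiseless segmentation recovers 25 measures and all 12 phase relations", {
  perf <- simulate_duet(score_spec(), tk0(), sh0(), seed = 1)
  si <- synchronization_index(relative_phase(cycle_phase(perf$streams$top),
                                             cycle_phase(perf$streams$bottom)))
  seg <- segment_by_si(si, threshold = 0.99, min_segment_s = 2)
  expect_equal(nrow(seg), 25L)
  expect_equal(seg$kind, rep(c("stable", "shifting"), length.out = 25L))
  stable_off <- seg$modal_offset[seg$kind == "stable"]
  expect_equal(stable_off, c(0:11, 0L))
  expect_equal(length(unique(stable_off[-13])), 12L)
})

test_that("a constant SI profile yields a single stable segment", {
  st <- iso_stream(2000)
  si <- synchronization_index(relative_phase(cycle_phase(st),
                                             cycle_phase(st)))
  seg <- segment_by_si(si)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$kind, "stable")
  expect_error(segment_by_si(si, threshold = 1.5), "threshold")
})

test_that("segmentation recovers the written form in most jittered runs", {
  # per-onset jitter at the 8 ms default is the noise source here
  jit <- function(role) performer_params(role, timing_jitter_sd_ms = 8,
                                         tempo_drift_sd = 0)
  res <- vapply(1:20, function(seed) {
    perf <- simulate_duet(score_spec(), jit("timekeeper"), jit("shifter"),
                          seed = seed)
    si <- synchronization_index(relative_phase(
      cycle_phase(perf$streams$top), cycle_phase(perf$streams$bottom)))
    seg <- segment_by_si(si)
    stable_off <- seg$modal_offset[seg$kind == "stable"]
    ok25 <- nrow(seg) == 25L
    asc <- ok25 && identical(stable_off, c(0:11, 0L))
    c(ok25, asc)
  }, logical(2))
  expect_gte(sum(res[1, ]), 18L)
  # whenever the count is recovered, the offsets ascend 0..11 and return
  expect_true(all(res[2, res[1, ]]))
})
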