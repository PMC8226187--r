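test_that("head PC1 recovers single-axis motion and normalizes its output", {
  t <- seq(0, 20, by = 1 / 60)
  osc <- sin(2 * pi * 1.2 * t)
  pos <- cbind(0.02 * osc, 0, 1.2 + 0 * t)
  pc <- head_pc1(pos, fs = 60)
  expect_gt(abs(stats::cor(pc$series, osc)), 1 - 1e-9)
  expect_equal(mean(pc$series), 0, tolerance = 1e-12)
  expect_equal(stats::sd(pc$series), 1, tolerance = 1e-12)
  expect_gt(pc$var_explained, 0.999)
  expect_error(head_pc1(matrix(1, 100, 3)), "degenerate")
})

test_that("isotropic noise spreads variance evenly across components", {
  set.seed(5)
  pos <- matrix(stats::rnorm(3e4), ncol = 3)
  pc <- head_pc1(pos)
  expect_lt(abs(pc$var_explained - 1 / 3), 0.05)
})

test_that("wavelet coherence is bounded, near 1 for self-coherence, and localizes a shared tone", {
  set.seed(42)
  fs <- 20
  t <- seq(0, 120, by = 1 / fs)
  x <- sin(2 * pi * 1.2 * t) + stats::rnorm(length(t), 0, 0.3)
  y <- sin(2 * pi * 1.2 * t + pi / 4) + stats::rnorm(length(t), 0, 0.3)
  m <- wavelet_coherence(x, y, fs)
  expect_true(all(m$coherence >= 0 & m$coherence <= 1))
  peak <- coherence_peak(m)
  expect_lt(abs(log2(peak$peak_hz / 1.2)), 1 / 12 + 1e-9)
  ms <- wavelet_coherence(x, x, fs)
  expect_gte(min(ms$coherence[ms$in_coi]), 0.99)
  expect_error(wavelet_coherence(x, y[-1], fs), "length")
  expect_error(wavelet_coherence(x[1:500], y[1:500], fs), "1024")
})

test_that("independent white noise shows low in-cone coherence", {
  meds <- vapply(1:20, function(s) {
    set.seed(600 + s)
    a <- stats::rnorm(1100)
    b <- stats::rnorm(1100)
    m <- wavelet_coherence(a, b, fs = 20)
    stats::median(m$coherence[m$in_coi])
  }, numeric(1))
  expect_lt(stats::median(meds), 0.4)
})

test_that("band phase statistics recover a quarter-period lag and rotate correctly", {
  fs <- 20
  t <- seq(0, 120, by = 1 / fs)
  x <- sin(2 * pi * 1.2 * t)
  y <- sin(2 * pi * 1.2 * (t - 1 / (4 * 1.2)))   # quarter period late
  m <- wavelet_coherence(x, y, fs)
  st <- band_phase_stats(m, band_hz = c(0.9, 1.5))
  expect_equal(st$mean_angle_deg, 90, tolerance = 2)
  expect_gt(st$resultant_length, 0.9)
  # rotation invariance of R; mean rotates with the angles
  m2 <- m
  m2$phase_rad <- ((m$phase_rad + pi / 6 + pi) %% (2 * pi)) - pi
  st2 <- band_phase_stats(m2, band_hz = c(0.9, 1.5))
  expect_equal(st2$resultant_length, st$resultant_length, tolerance = 1e-9)
  expect_equal(st2$mean_angle_deg, st$mean_angle_deg + 30, tolerance = 1e-6)
  expect_error(band_phase_stats(m, band_hz = c(10, 20)), "band")
})

test_that("degenerate angle sets behave as circular statistics require", {
  fake <- structure(list(time_s = 1:100 / 10, freq_hz = 1,
                         coherence = matrix(1, 1, 100),
                         phase_rad = matrix(0.7, 1, 100),
                         in_coi = matrix(TRUE, 1, 100), fs = 10),
                    class = "coherence_map")
  st <- band_phase_stats(fake, band_hz = c(0.5, 2))
  expect_equal(st$mean_angle_deg, 0.7 * 180 / pi, tolerance = 1e-9)
  expect_equal(st$resultant_length, 1, tolerance = 1e-12)
  set.seed(77)
  fake$phase_rad <- matrix(stats::runif(2000, -pi, pi), 1)
  fake$coherence <- matrix(1, 1, 2000)
  fake$in_coi <- matrix(TRUE, 1, 2000)
  fake$time_s <- 1:2000 / 10
  st2 <- band_phase_stats(fake, band_hz = c(0.5, 2))
  expect_lt(st2$resultant_length, 0.05)
})

test_that("gaze angle geometry: aligned, orthogonal, 60-degree seating, rotation invariance", {
  own <- c(0, 0, 1.2)
  partner <- own + 2 * c(sin(pi / 3), cos(pi / 3), 0)
  n <- 50
  fwd <- matrix(c(0, 1, 0), n, 3, byrow = TRUE)
  ga <- gaze_angle(fwd, own, partner)
  expect_equal(ga$angle_deg, rep(60, n), tolerance = 1e-9)
  u <- (partner - own) / sqrt(sum((partner - own)^2))
  at <- gaze_angle(matrix(u, n, 3, byrow = TRUE), own, partner)
  expect_equal(at$angle_deg, rep(0, n), tolerance = 1e-6)
  ortho <- gaze_angle(matrix(c(0, 0, 1), n, 3, byrow = TRUE), own, partner)
  expect_equal(ortho$angle_deg, rep(90, n), tolerance = 1e-9)
  # rigid rotation applied to gaze and positions leaves the angle unchanged
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  ga_rot <- gaze_angle(fwd %*% t(R), as.numeric(R %*% own),
                       as.numeric(R %*% partner))
  expect_equal(ga_rot$angle_deg, ga$angle_deg, tolerance = 1e-9)
  expect_error(gaze_angle(fwd, own, own), "geometry")
  # missing gaze propagates
  fwd[3, ] <- NA
  expect_true(is.na(gaze_angle(fwd, own, partner)$angle_deg[3]))
})

test_that("sway recurrence is normalized, symmetric, calibrated, and flags steps", {
  sw <- synth_sway_series(120, 40, 1)
  pressures <- cbind(sw$sway + 10, -sw$sway + 10, sw$sway / 2 + 10,
                     -sw$sway / 2 + 10) +
    matrix(stats::rnorm(4 * length(sw$sway), 0, 0.01), ncol = 4)
  out <- sway_recurrence(pressures, fs = 40)
  expect_lt(abs(out$achieved_rr - 0.10), 0.005)
  expect_equal(max(out$rp_norm), 1)
  expect_equal(unname(diag(out$rp_norm)), rep(0, nrow(out$rp_norm)))
  expect_equal(out$rp_norm, t(out$rp_norm), tolerance = 1e-12)
  if (out$metrics$tt > 0)
    expect_gte(out$metrics$tt * out$fs,
               max(2, round(out$cfg$vmin_s * out$fs)) - 1e-9)
  expect_error(sway_recurrence(matrix(1, 400, 4), fs = 40),
               "calibration error")
  # injected step change: windowed RR drops around the step
  set.seed(12)
  base <- stats::rnorm(2400, 0, 0.2)
  stepped <- base + rep(c(0, 6), each = 1200)
  pr <- cbind(stepped, stepped, stepped, stepped) / 4
  o2 <- sway_recurrence(pr, fs = 40, target_fs = 10)
  wr <- rqa_metrics(o2$rm, windowed = TRUE, window_s = 10, step_s = 2)$windowed
  t_step <- 1200 / 40
  straddle <- wr$rr[abs(wr$time_s - t_step) < 2]
  away <- wr$rr[abs(wr$time_s - t_step) > 15]
  expect_lt(max(straddle), min(away))
})

test_that("nod annotations round-trip and align to segment boundaries", {
  perf <- simulate_duet(small_score(), seed = 9)
  tr <- synthesize_motion(perf, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tr$nods, f, row.names = FALSE, quote = FALSE)
  si <- synchronization_index(relative_phase(
    cycle_phase(perf$streams$top), cycle_phase(perf$streams$bottom)))
  seg <- segment_by_si(si)
  nods <- read_nod_annotations(f, segments = seg)
  expect_equal(nrow(nods), nrow(tr$nods))
  # simulator nods sit at stable-bar starts: near an SI segment boundary
  # (threshold crossings shift boundaries by up to ~half an SI window)
  expect_true(all(abs(nods$boundary_offset_s) < 5))
  # empty file round trip
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("performer,time_s", f2)
  expect_equal(nrow(read_nod_annotations(f2)), 0L)
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("performer,time_s", "top,1.0", "top,notanumber"), f3)
  expect_error(read_nod_annotations(f3), "line")
})
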