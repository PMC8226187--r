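# Shared fixtures and independent oracles for the test suite.

# noiseless performer pairs
tk0 <- function() performer_params("timekeeper", timing_jitter_sd_ms = 0,
                                   tempo_drift_sd = 0)
sh0 <- function() performer_params("shifter", timing_jitter_sd_ms = 0,
                                   tempo_drift_sd = 0)

# a short schedule for fast end-to-end tests
small_score <- function() score_spec(n_relations = 2L)

# isochronous stream at 72 BPM (dotted-quarter beat, IOI 60/(72*6) s)
iso_stream <- function(n = 97, ioi = 60 / (72 * 6), id = "iso") {
  note_stream((seq_len(n) - 1L) * ioi, performer_id = id)
}

# Brute-force O(n^2) recurrence census: explicit loops, line-by-line run
# scanning. Independent of the package's vectorized implementation.
oracle_rqa <- function(R, theiler, lmin, vmin) {
  n <- nrow(R)
  denom <- 0L
  npts <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) <= theiler) next
    denom <- denom + 1L
    if (R[i, j]) npts <- npts + 1L
  }
  det_pts <- 0L
  for (d in seq.int(-(n - 1L), n - 1L)) {
    if (abs(d) <= theiler) next
    run <- 0L
    for (i in seq.int(max(1L, 1L + d), min(n, n + d))) {
      if (R[i, i - d]) run <- run + 1L
      else {
        if (run >= lmin) det_pts <- det_pts + run
        run <- 0L
      }
    }
    if (run >= lmin) det_pts <- det_pts + run
  }
  vlens <- integer(0)
  for (j in seq_len(n)) {
    run <- 0L
    for (i in seq_len(n)) {
      if (R[i, j] && abs(i - j) > theiler) run <- run + 1L
      else {
        if (run >= vmin) vlens <- c(vlens, run)
        run <- 0L
      }
    }
    if (run >= vmin) vlens <- c(vlens, run)
  }
  list(rr = if (denom > 0) npts / denom else 0,
       det = if (npts > 0) det_pts / npts else 0,
       tt = if (length(vlens)) mean(vlens) else 0)
}

# wrap a bare logical matrix as a recurrence_matrix object
rm_from_matrix <- function(mat, fs = 1, theiler = 0,
                           cfg = rqa_config(m = 1L, tau_s = 1 / fs,
                                            lmin_s = 2 / fs,
                                            vmin_s = 2 / fs,
                                            theiler_s = theiler / fs)) {
  structure(list(mat = mat, radius = cfg$radius, theiler = theiler,
                 fs = fs, cfg = cfg, thresholded = TRUE),
            class = "recurrence_matrix")
}
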