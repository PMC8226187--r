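# Morlet continuous wavelet transform and wavelet coherence with
# Torrence-Compo-style smoothing: Gaussian in time (SD = scale, the
# classic choice) and a boxcar over 0.6 octave in scale.

.morlet_cwt <- function(x, fs, scales, omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  xh <- stats::fft(x - mean(x))
  k <- 0:(n - 1)
  wk <- 2 * pi * ifelse(k <= n / 2, k, k - n) / (n * dt)
  W <- matrix(0i, nrow = length(scales), ncol = n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-(s * wk - omega0)^2 / 2) * (wk > 0)
    W[j, ] <- stats::fft(xh * psi, inverse = TRUE) / n
  }
  W
}

# normalized moving-average smoothing that keeps edges unattenuated
.smooth_time <- function(v, kernel) {
  num <- stats::filter(v, kernel, sides = 2)
  den <- stats::filter(rep(1, length(v)), kernel, sides = 2)
  out <- as.numeric(num / den)
  out[is.na(out)] <- v[is.na(out)]
  out
}

.smooth_tc <- function(M, fs, scales, scale_win) {
  # time: Gaussian, SD = scale seconds, per scale row
  for (j in seq_along(scales)) {
    sd_samp <- scales[j] * fs
    half <- max(1L, ceiling(3 * sd_samp))
    kern <- stats::dnorm(seq(-half, half), sd = sd_samp)
    kern <- kern / sum(kern)
    M[j, ] <- .smooth_time(M[j, ], kern)
  }
  # scale: boxcar over scale_win voices
  if (scale_win > 1L) {
    half <- scale_win %/% 2L
    out <- M
    for (j in seq_len(nrow(M))) {
      rows <- max(1L, j - half):min(nrow(M), j + half)
      out[j, ] <- colMeans(M[rows, , drop = FALSE])
    }
    M <- out
  }
  M
}

.smooth_tc_complex <- function(M, fs, scales, scale_win) {
  .smooth_tc(Re(M), fs, scales, scale_win) +
    1i * .smooth_tc(Im(M), fs, scales, scale_win)
}

#' Wavelet coherence between two series
#'
#' Morlet (omega0 = 6) continuous wavelet transforms on a geometric
#' frequency grid, coherence `|S(Wx conj(Wy))|^2 / (S|Wx|^2 S|Wy|^2)` with
#' smoothing S Gaussian in time (SD = scale) and boxcar over 0.6 octave
#' in scale, and the cross-spectrum argument as the local relative phase.
#' The cone of influence (e-folding time `sqrt(2) * scale` from either
#' edge) is marked; summaries should exclude out-of-cone cells.
#'
#' @param x,y numeric series of equal length (>= 1024 samples) at `fs`.
#' @param fs sampling rate, Hz.
#' @param freq_range frequency span in Hz (default 0.125--4).
#' @param voices voices per octave (default 12).
#' @param omega0 Morlet nondimensional frequency.
#' @return an object of class `coherence_map`: list with `time_s`,
#'   `freq_hz` (descending), `coherence` and `phase_rad` (freq x time),
#'   `in_coi` (logical), `fs`.
#' @export
wavelet_coherence <- function(x, y, fs, freq_range = c(0.125, 4),
                              voices = 12L, omega0 = 6) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("alignment error: series lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 1024L)
    stop("alignment error: need at least 1024 samples", call. = FALSE)
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))   # Fourier factor
  n_oct <- log2(freq_range[2] / freq_range[1])
  freqs <- freq_range[2] * 2^(-(0:ceiling(voices * n_oct)) / voices)
  freqs <- freqs[freqs >= freq_range[1] * 0.999]
  scales <- 1 / (ff * freqs)
  Wx <- .morlet_cwt(x, fs, scales, omega0)
  Wy <- .morlet_cwt(y, fs, scales, omega0)
  scale_win <- max(1L, round(0.6 * voices))
  inv_s <- 1 / scales
  Sxx <- .smooth_tc(Mod(Wx)^2 * inv_s, fs, scales, scale_win)
  Syy <- .smooth_tc(Mod(Wy)^2 * inv_s, fs, scales, scale_win)
  Sxy <- .smooth_tc_complex(Wx * Conj(Wy) * inv_s, fs, scales, scale_win)
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  coh <- pmin(pmax(coh, 0), 1)
  tt <- (seq_len(n) - 1L) / fs
  edge <- pmin(tt, tt[n] - tt)
  in_coi <- outer(sqrt(2) * scales, edge, FUN = "<=")
  structure(list(time_s = tt, freq_hz = freqs, coherence = coh,
                 phase_rad = Arg(Sxy), in_coi = in_coi, fs = fs),
            class = "coherence_map")
}

#' Band-limited circular statistics of coherence phase angles
#'
#' Circular mean direction and resultant length of the in-cone
#' cross-wavelet phase angles inside a frequency band, weighted by local
#' coherence by default (set `weighted = FALSE` for the unweighted
#' summary). Angles are reported in degrees in (-180, 180].
#'
#' @param map a [wavelet_coherence()] map.
#' @param band_hz frequency band `c(low, high)` in Hz.
#' @param weighted weight angles by coherence.
#' @return an object of class `circular_stats`: list with
#'   `mean_angle_deg`, `resultant_length`, `band_hz`, `n`.
#' @export
band_phase_stats <- function(map, band_hz = c(0.9, 1.5), weighted = TRUE) {
  stopifnot(inherits(map, "coherence_map"))
  rows <- which(map$freq_hz >= band_hz[1] & map$freq_hz <= band_hz[2])
  if (!length(rows))
    stop("band error: no frequency voices inside the band", call. = FALSE)
  sel <- map$in_coi[rows, , drop = FALSE]
  ang <- map$phase_rad[rows, , drop = FALSE][sel]
  w <- if (weighted) map$coherence[rows, , drop = FALSE][sel] else NULL
  st <- .circ_stats(ang, w)
  mean_deg <- st$mean * 180 / pi
  if (!is.na(mean_deg) && mean_deg <= -180) mean_deg <- mean_deg + 360
  structure(list(mean_angle_deg = mean_deg, resultant_length = st$R,
                 band_hz = band_hz, n = st$n),
            class = "circular_stats")
}

#' Time-averaged coherence spectrum and its peak
#'
#' Averages the coherence over in-cone times for each frequency and
#' reports the frequency of the maximum inside `search_range`.
#'
#' @param map a [wavelet_coherence()] map.
#' @param search_range frequency range to search, Hz.
#' @return list with `freq_hz`, `mean_coherence`, `peak_hz`.
#' @export
coherence_peak <- function(map, search_range = c(0.5, 3)) {
  stopifnot(inherits(map, "coherence_map"))
  avg <- vapply(seq_along(map$freq_hz), function(j) {
    sel <- map$in_coi[j, ]
    if (!any(sel)) return(NA_real_)
    mean(map$coherence[j, sel])
  }, numeric(1))
  inside <- which(map$freq_hz >= search_range[1] &
                    map$freq_hz <= search_range[2] & !is.na(avg))
  if (!length(inside))
    stop("band error: no in-cone frequencies in the search range",
         call. = FALSE)
  peak <- inside[which.max(avg[inside])]
  list(freq_hz = map$freq_hz, mean_coherence = avg,
       peak_hz = map$freq_hz[peak])
}
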