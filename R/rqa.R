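#' Recurrence-analysis configuration
#'
#' Parameters of delay embedding and recurrence quantification. Defaults
#' follow the phase-series analysis (m = 4, tau = 0.3 s, radius 0.55,
#' minimum line lengths 0.3 s); postural sway uses m = 5, tau = 0.35 s with
#' the radius calibrated to the recurrence target (see
#' [calibrate_radius()]).
#'
#' @param m embedding dimension (>= 1).
#' @param tau_s embedding delay, seconds.
#' @param radius recurrence threshold (Euclidean norm).
#' @param lmin_s minimal diagonal line length for DET, seconds.
#' @param vmin_s minimal vertical line length for TT, seconds.
#' @param theiler_s half-width of the line-of-identity exclusion band,
#'   seconds; default `m * tau_s`.
#' @param target_rr target recurrence rate for radius calibration.
#' @return an object of class `rqa_config`.
#' @export
rqa_config <- function(m = 4L, tau_s = 0.3, radius = 0.55,
                       lmin_s = 0.3, vmin_s = 0.3,
                       theiler_s = m * tau_s, target_rr = 0.10) {
  if (!.is_count(m) || m < 1) .stop_config("m", "must be a positive integer")
  if (!.is_num1(tau_s) || tau_s <= 0) .stop_config("tau_s", "must be > 0")
  if (!.is_num1(radius) || radius <= 0) .stop_config("radius", "must be > 0")
  if (!.is_num1(lmin_s) || lmin_s <= 0) .stop_config("lmin_s", "must be > 0")
  if (!.is_num1(vmin_s) || vmin_s <= 0) .stop_config("vmin_s", "must be > 0")
  if (!.is_num1(theiler_s) || theiler_s < 0)
    .stop_config("theiler_s", "must be >= 0")
  if (!.is_num1(target_rr) || target_rr <= 0 || target_rr >= 1)
    .stop_config("target_rr", "must lie in (0, 1)")
  structure(list(m = as.integer(m), tau_s = tau_s, radius = radius,
                 lmin_s = lmin_s, vmin_s = vmin_s, theiler_s = theiler_s,
                 target_rr = target_rr),
            class = "rqa_config")
}

# Delay embedding of a (possibly multi-channel) series: rows are embedded
# state vectors, columns the m delayed copies of each channel.
.delay_embed <- function(x, m, tau) {
  x <- as.matrix(x)
  n <- nrow(x)
  n_emb <- n - (m - 1L) * tau
  if (n_emb < 10L)
    stop("length error: series too short for the requested embedding",
         call. = FALSE)
  cols <- lapply(seq_len(ncol(x)), function(ch)
    vapply(0:(m - 1L), function(k) x[(1L + k * tau):(k * tau + n_emb), ch],
           numeric(n_emb)))
  do.call(cbind, cols)
}

#' Recurrence matrix of a time series
#'
#' Delay-embeds the series with `(m, tau)` and marks pairs of embedded
#' states whose Euclidean distance is at most `radius`. Circular series
#' (phases) are first mapped to the unit circle `(cos, sin)` so that wrap
#' discontinuities do not create spurious non-recurrences. Entries within
#' the Theiler band `|i - j| <= theiler` are excluded from every metric.
#'
#' @param x numeric series (or a `phase_series` with `circular = TRUE`).
#' @param cfg an [rqa_config()].
#' @param fs sampling rate in Hz (taken from `x` if it is a series object).
#' @param circular map the series to `(cos, sin)` before embedding.
#' @param threshold if `FALSE`, return the unthresholded distance matrix.
#' @return object of class `recurrence_matrix`: list with `mat` (logical,
#'   or numeric distances when unthresholded), `radius`, `theiler`
#'   (samples), `fs`, `cfg`, `thresholded`.
#' @export
recurrence_matrix <- function(x, cfg = rqa_config(), fs = NULL,
                              circular = FALSE, threshold = TRUE) {
  if (inherits(x, "phase_series")) {
    if (is.null(fs)) fs <- x$fs
    x <- x$phase_rad
    circular <- TRUE
  }
  if (is.null(fs)) stop("fs is required for a bare numeric series",
                        call. = FALSE)
  tau <- max(1L, round(cfg$tau_s * fs))
  xs <- if (circular) cbind(cos(x), sin(x)) else as.matrix(x)
  emb <- .delay_embed(xs, cfg$m, tau)
  d <- as.matrix(stats::dist(emb))
  theiler <- round(cfg$theiler_s * fs)
  mat <- if (threshold) d <= cfg$radius else d
  structure(list(mat = mat, radius = if (threshold) cfg$radius else NA_real_,
                 theiler = theiler, fs = fs, cfg = cfg,
                 thresholded = threshold),
            class = "recurrence_matrix")
}

#' Joint recurrence plot
#'
#' Elementwise conjunction of two thresholded recurrence matrices:
#' a joint recurrence is a time pair at which both systems recur.
#'
#' @param r1,r2 [recurrence_matrix()] objects of equal size.
#' @return a `recurrence_matrix` holding the joint plot.
#' @export
joint_recurrence <- function(r1, r2) {
  stopifnot(inherits(r1, "recurrence_matrix"),
            inherits(r2, "recurrence_matrix"))
  if (!r1$thresholded || !r2$thresholded)
    stop("joint recurrence needs thresholded matrices", call. = FALSE)
  if (!identical(dim(r1$mat), dim(r2$mat)))
    stop("alignment error: recurrence matrices differ in size", call. = FALSE)
  out <- r1
  out$mat <- r1$mat & r2$mat
  out$theiler <- max(r1$theiler, r2$theiler)
  out
}

# Linear indices of the diagonal with offset d = row - col.
.diag_idx <- function(n, d) {
  i <- seq.int(max(1L, 1L + d), min(n, n + d))
  i + (i - d - 1L) * n
}

# Metric kernel on a logical matrix with Theiler exclusion.
.rqa_census <- function(R, theiler, lmin, vmin) {
  n <- nrow(R)
  band <- seq.int(-min(theiler, n - 1L), min(theiler, n - 1L))
  for (d in band) R[.diag_idx(n, d)] <- FALSE
  denom <- n * n - sum(n - abs(band))
  npts <- sum(R)
  rr <- if (denom > 0) npts / denom else 0
  # diagonal line census
  det_pts <- 0
  for (d in seq.int(-(n - 1L), n - 1L)) {
    if (abs(d) <= theiler) next
    v <- R[.diag_idx(n, d)]
    if (!any(v)) next
    r <- rle(v)
    keep <- r$values & r$lengths >= lmin
    det_pts <- det_pts + sum(r$lengths[keep])
  }
  det <- if (npts > 0) det_pts / npts else 0
  # vertical line census
  vlen <- integer(0)
  for (j in seq_len(n)) {
    v <- R[, j]
    if (!any(v)) next
    r <- rle(v)
    vlen <- c(vlen, r$lengths[r$values & r$lengths >= vmin])
  }
  tt <- if (length(vlen)) mean(vlen) else 0
  list(rr = rr, det = det, tt = tt, n_points = npts)
}

#' Recurrence quantification metrics
#'
#' Computes the recurrence rate (fraction of recurrent points outside the
#' Theiler band), determinism (fraction of recurrent points lying on
#' diagonal lines of at least `lmin_s`) and trapping time (mean vertical
#' line length among verticals of at least `vmin_s`; 0 when none survive).
#' With `windowed = TRUE` the same metrics are computed inside square
#' windows sliding along the main diagonal (fully interior windows only).
#'
#' @param rm a thresholded [recurrence_matrix()] or [joint_recurrence()].
#' @param windowed compute a windowed profile as well.
#' @param window_s,step_s window length and hop along the diagonal, seconds.
#' @return object of class `rqa_metrics`: list with `rr`, `det`, `tt`
#'   (seconds) and, if requested, `windowed` (data frame `time_s`, `rr`,
#'   `det`, `tt`).
#' @export
rqa_metrics <- function(rm, windowed = FALSE, window_s = 10, step_s = 1) {
  stopifnot(inherits(rm, "recurrence_matrix"))
  if (!rm$thresholded)
    stop("rqa_metrics needs a thresholded matrix", call. = FALSE)
  fs <- rm$fs
  lmin <- max(2L, round(rm$cfg$lmin_s * fs))
  vmin <- max(2L, round(rm$cfg$vmin_s * fs))
  cen <- .rqa_census(rm$mat, rm$theiler, lmin, vmin)
  out <- list(rr = cen$rr, det = cen$det, tt = cen$tt / fs)
  if (windowed) {
    n <- nrow(rm$mat)
    w <- round(window_s * fs)
    step <- max(1L, round(step_s * fs))
    starts <- seq(1L, n - w + 1L, by = step)
    prof <- lapply(starts, function(a) {
      sub <- rm$mat[a:(a + w - 1L), a:(a + w - 1L), drop = FALSE]
      cc <- .rqa_census(sub, rm$theiler, lmin, vmin)
      c(rr = cc$rr, det = cc$det, tt = cc$tt / fs)
    })
    prof <- do.call(rbind, prof)
    out$windowed <- data.frame(
      time_s = (starts - 1L + w / 2) / fs,
      rr = prof[, "rr"], det = prof[, "det"], tt = prof[, "tt"])
  }
  class(out) <- "rqa_metrics"
  out
}

#' @export
print.rqa_metrics <- function(x, ...) {
  cat(sprintf("<rqa_metrics: RR %.4f, DET %.4f, TT %.3f s>\n",
              x$rr, x$det, x$tt))
  invisible(x)
}

#' Calibrate the recurrence radius to a target recurrence rate
#'
#' Bisects the radius between 0 and the maximum pairwise embedded distance
#' until the recurrence rate (off the Theiler band) is within `tol` of
#' `target_rr`. RR is monotone non-decreasing in the radius, so bisection
#' converges; a constant (degenerate) series has no usable distances and
#' signals a calibration error.
#'
#' @param x numeric series (or `phase_series`).
#' @param cfg an [rqa_config()]; its `target_rr` is the default target.
#' @param fs sampling rate, Hz.
#' @param target_rr target recurrence rate in (0, 0.5).
#' @param tol tolerance on the achieved RR.
#' @param circular embed on the unit circle (see [recurrence_matrix()]).
#' @return list with `radius`, `rr` (achieved), `iterations`.
#' @export
calibrate_radius <- function(x, cfg = rqa_config(), fs = NULL,
                             target_rr = cfg$target_rr, tol = 0.005,
                             circular = FALSE) {
  if (inherits(x, "phase_series")) {
    if (is.null(fs)) fs <- x$fs
    x <- x$phase_rad
    circular <- TRUE
  }
  if (is.null(fs)) stop("fs is required", call. = FALSE)
  if (target_rr <= 0 || target_rr >= 0.5)
    .stop_config("target_rr", "must lie in (0, 0.5)")
  tau <- max(1L, round(cfg$tau_s * fs))
  xs <- if (circular) cbind(cos(x), sin(x)) else as.matrix(x)
  emb <- .delay_embed(xs, cfg$m, tau)
  d <- stats::dist(emb)
  n <- attr(d, "Size")
  theiler <- round(cfg$theiler_s * fs)
  # |i - j| for the lower-triangle dist ordering
  gap <- sequence(seq.int(n - 1L, 1L))
  dv <- as.numeric(d)[gap > theiler]
  if (!length(dv) || max(dv) <= 0)
    stop("calibration error: degenerate (constant) series", call. = FALSE)
  lo <- 0; hi <- max(dv); rr <- NA_real_; mid <- hi / 2
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    rr <- mean(dv <= mid)
    if (abs(rr - target_rr) <= tol) break
    if (rr < target_rr) lo <- mid else hi <- mid
  }
  list(radius = mid, rr = rr, iterations = it)
}
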