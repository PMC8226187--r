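#' First principal component of 3D head motion
#'
#' Centers the 3D position columns, projects onto the first principal
#' axis and z-scores the projection. The axis sign is fixed so that the
#' loading of largest magnitude is positive, making the series
#' reproducible across runs.
#'
#' @param head_pos n x 3 numeric matrix of positions (one performer).
#' @param fs sampling rate in Hz (carried through for downstream use).
#' @return list with `series` (z-scored PC1), `loading` (unit 3-vector),
#'   `var_explained`, `fs`.
#' @export
head_pc1 <- function(head_pos, fs = NULL) {
  head_pos <- as.matrix(head_pos)
  stopifnot(ncol(head_pos) == 3L)
  if (nrow(head_pos) < 3L || !all(is.finite(head_pos)))
    stop("head positions must be finite with >= 3 samples", call. = FALSE)
  vars <- apply(head_pos, 2, stats::var)
  if (all(vars == 0))
    stop("degenerate motion: head position is constant", call. = FALSE)
  pc <- stats::prcomp(head_pos, center = TRUE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  if (load1[which.max(abs(load1))] < 0) load1 <- -load1
  sc <- as.numeric(scale(head_pos, center = TRUE, scale = FALSE) %*% load1)
  s <- stats::sd(sc)
  if (s == 0)
    stop("degenerate motion: first principal component is constant",
         call. = FALSE)
  list(series = (sc - mean(sc)) / s, loading = load1,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2), fs = fs)
}

#' Angle between gaze direction and the partner's head
#'
#' For each sample, the angle (degrees) between the gaze unit vector and
#' the unit vector from the performer's own head to the partner's head.
#' Missing gaze samples propagate as NA.
#'
#' @param gaze_dir n x 3 matrix of unit gaze vectors.
#' @param own_head_pos n x 3 matrix (or length-3 vector) of own head
#'   positions.
#' @param partner_head_pos n x 3 matrix (or length-3 vector) of partner
#'   head positions.
#' @param time_s optional time grid carried into the result.
#' @return an object of class `gaze_series`: data frame with `time_s`
#'   (if given) and `angle_deg` in [0, 180].
#' @export
gaze_angle <- function(gaze_dir, own_head_pos, partner_head_pos,
                       time_s = NULL) {
  gaze_dir <- as.matrix(gaze_dir)
  n <- nrow(gaze_dir)
  as_mat <- function(p) {
    if (is.null(dim(p))) matrix(p, nrow = n, ncol = 3, byrow = TRUE)
    else as.matrix(p)
  }
  own <- as_mat(own_head_pos); partner <- as_mat(partner_head_pos)
  u <- partner - own
  nrm <- sqrt(rowSums(u^2))
  if (any(nrm[is.finite(nrm)] == 0))
    stop("geometry error: zero-length head-to-partner vector",
         call. = FALSE)
  u <- u / nrm
  g <- gaze_dir / sqrt(rowSums(gaze_dir^2))
  d <- pmin(pmax(rowSums(g * u), -1), 1)
  out <- data.frame(angle_deg = acos(d) * 180 / pi)
  if (!is.null(time_s)) out <- cbind(data.frame(time_s = time_s), out)
  class(out) <- c("gaze_series", "data.frame")
  out
}

#' Postural-sway recurrence analysis
#'
#' Sums the four chair-pressure channels into one sway series, z-scores
#' it, and builds (i) a normalized unthresholded recurrence plot (pairwise
#' embedded distances divided by their maximum) and (ii) thresholded RQA
#' metrics at a radius calibrated to the recurrence target. Sway is slow,
#' so the series is decimated (boxcar + subsample) to `target_fs` before
#' embedding to keep the plot tractable.
#'
#' @param pressures n x 4 matrix of pressure channels.
#' @param fs sampling rate of `pressures`, Hz.
#' @param cfg an [rqa_config()]; sway defaults are m = 5, tau = 0.35 s.
#' @param target_fs decimated rate for the recurrence analysis, Hz.
#' @param target_rr recurrence target for radius calibration.
#' @return list with `sway` (decimated z-scored series), `fs` (decimated),
#'   `rp_norm` (normalized unthresholded distances in [0, 1]), `radius`,
#'   `metrics` (an `rqa_metrics`), `cfg`.
#' @export
sway_recurrence <- function(pressures, fs,
                            cfg = rqa_config(m = 5L, tau_s = 0.35),
                            target_fs = 10, target_rr = cfg$target_rr) {
  pressures <- as.matrix(pressures)
  stopifnot(ncol(pressures) == 4L)
  if (!all(is.finite(pressures)))
    stop("sway channels must be finite", call. = FALSE)
  sway <- rowSums(pressures)
  dec <- max(1L, round(fs / target_fs))
  if (dec > 1L) {
    sway <- as.numeric(stats::filter(sway, rep(1 / dec, dec), sides = 2))
    sway <- sway[seq(ceiling(dec / 2), length(sway), by = dec)]
    sway <- sway[is.finite(sway)]
  }
  fs_d <- fs / dec
  s <- stats::sd(sway)
  if (is.na(s) || s == 0)
    stop("calibration error: degenerate (constant) sway series",
         call. = FALSE)
  sway <- (sway - mean(sway)) / s
  tau <- max(1L, round(cfg$tau_s * fs_d))
  emb <- .delay_embed(as.matrix(sway), cfg$m, tau)
  d <- as.matrix(stats::dist(emb))
  dmax <- max(d)
  if (dmax == 0)
    stop("calibration error: degenerate (constant) sway series",
         call. = FALSE)
  cal <- calibrate_radius(sway, cfg, fs = fs_d, target_rr = target_rr)
  cfg_cal <- cfg
  cfg_cal$radius <- cal$radius
  rm <- structure(list(mat = d <= cal$radius, radius = cal$radius,
                       theiler = round(cfg$theiler_s * fs_d), fs = fs_d,
                       cfg = cfg_cal, thresholded = TRUE),
                  class = "recurrence_matrix")
  list(sway = sway, fs = fs_d, rp_norm = d / dmax, radius = cal$radius,
       achieved_rr = cal$rr, metrics = rqa_metrics(rm), rm = rm,
       cfg = cfg_cal)
}
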