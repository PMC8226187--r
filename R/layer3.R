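#' Questionnaire bundle for one condition
#'
#' Structural container for the post-condition self-reports: a 10-item
#' flow short scale, presence items keyed to subscales, three extra
#' presence items and three custom interaction items, all on 1--7 Likert
#' scales. Item texts of the published instruments are not redistributed;
#' the scales are defined structurally.
#'
#' @param flow_items numeric vector of 10 ratings in 1--7.
#' @param presence_items named list of numeric rating vectors, one per
#'   subscale (e.g. `involvement`, `immersion`, `interface_quality`,
#'   `sensory_fidelity`), each in 1--7.
#' @param extra_items named numeric vector with elements `being_there`,
#'   `spatial_presence`, `similarity_real_place` (1--7).
#' @param custom_items named numeric vector with elements `enjoyment`,
#'   `closeness`, `naturalness` (1--7).
#' @param condition condition label, e.g. `"human"`, `"avatar"`, `"agent"`.
#' @return an object of class `questionnaire_bundle`.
#' @export
questionnaire_bundle <- function(flow_items,
                                 presence_items = list(),
                                 extra_items = c(being_there = NA_real_,
                                                 spatial_presence = NA_real_,
                                                 similarity_real_place = NA_real_),
                                 custom_items = c(enjoyment = NA_real_,
                                                  closeness = NA_real_,
                                                  naturalness = NA_real_),
                                 condition = "human") {
  check_scale <- function(x, what) {
    bad <- which(is.finite(x) & (x < 1 | x > 7))
    if (length(bad))
      stop(sprintf("validation error: %s item %d = %g outside 1..7",
                   what, bad[1], x[bad[1]]), call. = FALSE)
  }
  if (length(flow_items) != 10L)
    stop("validation error: flow_items must have 10 items", call. = FALSE)
  check_scale(flow_items, "flow")
  for (nm in names(presence_items))
    check_scale(presence_items[[nm]], paste0("presence/", nm))
  check_scale(extra_items, "extra")
  check_scale(custom_items, "custom")
  structure(list(flow_items = as.numeric(flow_items),
                 presence_items = lapply(presence_items, as.numeric),
                 extra_items = extra_items, custom_items = custom_items,
                 condition = condition),
            class = "questionnaire_bundle")
}

#' Score a questionnaire bundle
#'
#' Flow score is the arithmetic mean of the 10 flow items; presence
#' subscale scores are per-subscale means plus a grand mean over all
#' presence items; extra and custom items pass through verbatim.
#' Reverse-keyed items (rating `x` becomes `8 - x`) are handled through
#' `reverse_keys`, a named list of item indices per scale.
#'
#' @param bundle a [questionnaire_bundle()].
#' @param reverse_keys named list, e.g. `list(flow = c(3, 7), involvement
#'   = 2)`, giving 1-based indices of reverse-keyed items.
#' @param flow_subscales optional named list of index vectors splitting
#'   the flow scale (e.g. fluency/absorption); means are reported per key.
#' @return list with `condition`, `flow_mean`, `flow_subscales` (or NULL),
#'   `presence` (named subscale means), `presence_grand_mean`,
#'   `extra_items`, `custom_items`.
#' @export
score_questionnaires <- function(bundle, reverse_keys = list(),
                                 flow_subscales = NULL) {
  stopifnot(inherits(bundle, "questionnaire_bundle"))
  rev_apply <- function(x, idx) { x[idx] <- 8 - x[idx]; x }
  flow <- rev_apply(bundle$flow_items,
                    reverse_keys$flow %||% integer(0))
  pres <- bundle$presence_items
  for (nm in names(pres))
    pres[[nm]] <- rev_apply(pres[[nm]], reverse_keys[[nm]] %||% integer(0))
  list(condition = bundle$condition,
       flow_mean = mean(flow),
       flow_subscales = if (!is.null(flow_subscales))
         vapply(flow_subscales, function(i) mean(flow[i]), numeric(1)),
       presence = vapply(pres, mean, numeric(1)),
       presence_grand_mean = if (length(pres))
         mean(unlist(pres)) else NA_real_,
       extra_items = bundle$extra_items,
       custom_items = bundle$custom_items)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a pupil-diameter series
#'
#' Blink and artifact removal by a dilation-speed filter (samples whose
#' absolute sample-to-sample speed deviates from the median by more than 3
#' median absolute deviations are dropped, together with samples already
#' missing), linear interpolation of gaps shorter than `max_gap_s`, and a
#' z-score over the valid samples. Longer gaps stay missing: the result is
#' an attention/arousal proxy comparable only within one recording.
#'
#' @param time_s uniform time grid, seconds.
#' @param diameter_mm pupil diameter, mm, with NA for missing samples.
#' @param max_gap_s longest gap to interpolate, seconds.
#' @param min_valid_s minimum total valid data required, seconds.
#' @return an object of class `pupil_series`: list with `time_s`,
#'   `diameter_mm` (raw), `normalized` (mean 0, SD 1 over valid samples),
#'   `valid` (logical), `fs`.
#' @export
normalize_pupil <- function(time_s, diameter_mm, max_gap_s = 0.5,
                            min_valid_s = 30) {
  stopifnot(length(time_s) == length(diameter_mm))
  dt <- stats::median(diff(time_s))
  fs <- 1 / dt
  x <- diameter_mm
  speed <- c(NA, abs(diff(x)) / dt)
  med <- stats::median(speed, na.rm = TRUE)
  mad <- stats::mad(speed, na.rm = TRUE)
  if (is.finite(mad) && mad > 0) {
    spike <- which(speed - med > 3 * mad)
    x[unique(c(spike, spike - 1L))] <- NA_real_
  }
  # a speed filter only flags blink edges; the occluded samples between
  # them sit at implausible diameters and are caught on amplitude
  amp_med <- stats::median(x, na.rm = TRUE)
  amp_mad <- stats::mad(x, na.rm = TRUE)
  if (is.finite(amp_mad) && amp_mad > 0)
    x[abs(x - amp_med) > 3 * amp_mad] <- NA_real_
  if (sum(!is.na(x)) * dt < min_valid_s)
    stop("insufficient data: fewer than ", min_valid_s,
         " s of valid pupil samples", call. = FALSE)
  # interpolate short gaps only
  filled <- stats::approx(time_s[!is.na(x)], x[!is.na(x)], xout = time_s,
                          rule = 1, ties = "ordered")$y
  gap_id <- cumsum(c(TRUE, diff(is.na(x)) != 0))
  for (g in unique(gap_id[is.na(x)])) {
    idx <- which(gap_id == g & is.na(x))
    if (length(idx) * dt >= max_gap_s) filled[idx] <- NA_real_
  }
  valid <- !is.na(filled)
  z <- filled
  z[valid] <- (filled[valid] - mean(filled[valid])) / stats::sd(filled[valid])
  structure(list(time_s = time_s, diameter_mm = diameter_mm,
                 normalized = z, valid = valid, fs = fs),
            class = "pupil_series")
}
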