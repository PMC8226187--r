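#' Score specification for a phasing performance
#'
#' Describes the compositional schedule of a Piano-Phase-style duet: a
#' repeating pattern of `pattern_length` sixteenth notes, played in unison,
#' then shifted ahead one sixteenth at a time by the second performer until
#' all `n_relations` phase relations have been traversed and the parts
#' return to unison. Stable bars hold `reps_per_bar` repetitions of the
#' pattern at a constant tempo; shifting bars last `shift_duration_s`
#' seconds during which the second part gains exactly one sixteenth.
#'
#' @param pattern_pitches MIDI note numbers of the repeating pattern
#'   (onsets, not pitch content, drive every analysis; defaults are
#'   placeholders).
#' @param reps_per_bar pattern repetitions per stable bar.
#' @param tempo_bpm base tempo in beats per minute (dotted-quarter beat).
#' @param sixteenths_per_beat sixteenths per beat (6 = dotted quarter).
#' @param n_relations number of one-sixteenth phase relations to traverse.
#' @param shift_duration_s seconds per one-sixteenth shift. The score's
#'   guidance of roughly 30--60 s per shift is a valid setting; the
#'   default of 10 s keeps simulated runs short.
#' @return an object of class `score_spec`.
#' @export
score_spec <- function(pattern_pitches = 60:71,
                       reps_per_bar = 8L,
                       tempo_bpm = 72,
                       sixteenths_per_beat = 6L,
                       n_relations = 12L,
                       shift_duration_s = 10) {
  if (!is.numeric(pattern_pitches) || length(pattern_pitches) != 12L)
    .stop_config("pattern_pitches", "must be 12 MIDI note numbers")
  if (!.is_count(reps_per_bar) || reps_per_bar < 1)
    .stop_config("reps_per_bar", "must be a positive integer")
  if (!.is_num1(tempo_bpm) || tempo_bpm <= 0)
    .stop_config("tempo_bpm", "must be > 0")
  if (!.is_count(sixteenths_per_beat) || sixteenths_per_beat < 1)
    .stop_config("sixteenths_per_beat", "must be a positive integer")
  if (!.is_count(n_relations) || n_relations < 1)
    .stop_config("n_relations", "must be a positive integer")
  if (!.is_num1(shift_duration_s) || shift_duration_s <= 0)
    .stop_config("shift_duration_s", "must be > 0")
  structure(list(
    pattern_pitches = as.integer(pattern_pitches),
    pattern_length = 12L,
    reps_per_bar = as.integer(reps_per_bar),
    tempo_bpm = as.numeric(tempo_bpm),
    sixteenths_per_beat = as.integer(sixteenths_per_beat),
    n_relations = as.integer(n_relations),
    shift_duration_s = as.numeric(shift_duration_s)
  ), class = "score_spec")
}

#' Generate the bar schedule of a phasing performance
#'
#' Expands a [score_spec()] into its bar-by-bar schedule: `2 * n_relations
#' + 1` bars alternating stable / shifting, with the target offset (in
#' sixteenth notes, of the second part ahead of the first) ascending
#' 0, 1, ..., `n_relations` across the stable bars. With 12 relations the
#' final stable bar is back at unison (offset 12 = 0 mod 12).
#'
#' @param config a [score_spec()].
#' @return a data frame of class `duet_schedule` with columns `index`,
#'   `kind` (`"stable"` or `"shifting"`), `target_offset_sixteenths`,
#'   `start_s`, `end_s`.
#' @examples
#' sched <- generate_score(score_spec())
#' nrow(sched)        # 25 bars
#' table(sched$kind)  # 13 stable, 12 shifting
#' @export
generate_score <- function(config = score_spec()) {
  stopifnot(inherits(config, "score_spec"))
  six <- sixteenth_duration(config$tempo_bpm, config$sixteenths_per_beat)
  stable_dur <- config$reps_per_bar * config$pattern_length * six
  nb <- 2L * config$n_relations + 1L
  kind <- rep(c("stable", "shifting"), length.out = nb)
  # offset held during stable bar k is k-1 sixteenths (0-based); a shifting
  # bar ramps from its predecessor's offset to its successor's.
  stable_idx <- cumsum(kind == "stable")
  offset <- ifelse(kind == "stable", stable_idx - 1L, stable_idx)
  dur <- ifelse(kind == "stable", stable_dur, config$shift_duration_s)
  end_s <- cumsum(dur)
  start_s <- end_s - dur
  out <- data.frame(
    index = seq_len(nb),
    kind = kind,
    target_offset_sixteenths = as.integer(offset),
    start_s = start_s,
    end_s = end_s,
    stringsAsFactors = FALSE
  )
  class(out) <- c("duet_schedule", "data.frame")
  attr(out, "score") <- config
  out
}

# Second part's target offset (in sixteenths, possibly fractional during a
# shifting bar) as a piecewise-linear function of time.
.offset_at <- function(schedule, t) {
  off <- numeric(length(t))
  for (i in seq_len(nrow(schedule))) {
    b <- schedule[i, ]
    sel <- t >= b$start_s & (t < b$end_s | i == nrow(schedule))
    if (!any(sel)) next
    if (b$kind == "stable") {
      off[sel] <- b$target_offset_sixteenths
    } else {
      frac <- (t[sel] - b$start_s) / (b$end_s - b$start_s)
      off[sel] <- (b$target_offset_sixteenths - 1) + frac
    }
  }
  off[t >= schedule$end_s[nrow(schedule)]] <-
    schedule$target_offset_sixteenths[nrow(schedule)]
  off
}
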