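#' Note-onset stream for one performer
#'
#' Minimal performance record used throughout the analysis layers: note-on
#' times in seconds (strictly increasing), MIDI note numbers and velocities.
#'
#' @param onsets_s numeric, strictly increasing onset times in seconds.
#' @param pitches integer MIDI note numbers (0--127), recycled to length.
#' @param velocities integer velocities (1--127), recycled to length.
#' @param performer_id character label.
#' @return an object of class `note_stream`.
#' @export
note_stream <- function(onsets_s, pitches = 60L, velocities = 80L,
                        performer_id = "p") {
  onsets_s <- as.numeric(onsets_s)
  if (length(onsets_s) && any(diff(onsets_s) <= 0))
    stop("onsets_s must be strictly increasing", call. = FALSE)
  n <- length(onsets_s)
  pitches <- rep_len(as.integer(pitches), n)
  velocities <- rep_len(as.integer(velocities), n)
  if (n && (any(velocities < 1) || any(velocities > 127)))
    stop("velocities must lie in 1..127", call. = FALSE)
  structure(list(onsets_s = onsets_s, pitches = pitches,
                 velocities = velocities, performer_id = performer_id),
            class = "note_stream")
}

#' @export
print.note_stream <- function(x, ...) {
  cat(sprintf("<note_stream '%s': %d onsets", x$performer_id,
              length(x$onsets_s)))
  if (length(x$onsets_s))
    cat(sprintf(", %.3f..%.3f s", min(x$onsets_s), max(x$onsets_s)))
  cat(">\n")
  invisible(x)
}

#' @export
length.note_stream <- function(x) length(x$onsets_s)
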