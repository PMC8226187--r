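.wrap_2pi <- function(x) x %% (2 * pi)

.wrap_pi <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.stop_config <- function(field, why) {
  stop(sprintf("invalid configuration: `%s` %s", field, why), call. = FALSE)
}

#' Duration of one sixteenth note
#'
#' At `tempo_bpm` beats per minute with `sixteenths_per_beat` sixteenths to
#' the beat (the dotted-quarter convention uses 6), one sixteenth lasts
#' `60 / (tempo_bpm * sixteenths_per_beat)` seconds.
#'
#' @param tempo_bpm tempo in beats per minute.
#' @param sixteenths_per_beat number of sixteenth notes per beat.
#' @return duration of a sixteenth note in seconds.
#' @export
sixteenth_duration <- function(tempo_bpm, sixteenths_per_beat = 6L) {
  60 / (tempo_bpm * sixteenths_per_beat)
}

# Deterministic sub-stream seeds: one master seed per simulate call, offsets
# per signal, kept below 2^31.
.substream_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}

# Circular mean/resultant of angles (radians), optionally weighted.
.circ_stats <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  keep <- is.finite(theta) & is.finite(w)
  theta <- theta[keep]; w <- w[keep]
  if (!length(theta)) return(list(mean = NA_real_, R = NA_real_, n = 0L))
  z <- sum(w * exp(1i * theta)) / sum(w)
  list(mean = Arg(z), R = Mod(z), n = length(theta))
}

# Mode of an integer vector (ties -> smallest).
.modal_int <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}
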