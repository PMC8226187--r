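# Standard MIDI File I/O. Format 1 on write (tempo track + one note track,
# 480 ticks per quarter note); formats 0 and 1 on read, with running
# status, velocity-0 note-ons treated as note-offs, and a piecewise tempo
# map built from tempo meta events across all tracks.

.TPQ <- 480L

.varint_encode <- function(x) {
  x <- as.integer(x)
  out <- as.raw(x %% 128L)
  x <- x %/% 128L
  while (x > 0L) {
    out <- c(as.raw(bitwOr(x %% 128L, 128L)), out)
    x <- x %/% 128L
  }
  out
}

.u32 <- function(x) as.raw(c(x %/% 16777216L, (x %/% 65536L) %% 256L,
                             (x %/% 256L) %% 256L, x %% 256L))
.u16 <- function(x) as.raw(c(x %/% 256L, x %% 256L))
.u24 <- function(x) as.raw(c(x %/% 65536L, (x %/% 256L) %% 256L, x %% 256L))

#' Write a note stream as a Standard MIDI File
#'
#' Format-1 file with 480 ticks per quarter note: track 0 holds the tempo
#' meta event, track 1 the note events (note-on velocity > 0 at each onset,
#' note-off half a sixteenth later). The beat is a dotted quarter (six
#' sixteenths), so the MIDI quarter-note rate is `tempo_bpm *
#' sixteenths_per_beat / 4` QPM.
#'
#' @param stream a [note_stream()] (may be empty).
#' @param path output file path.
#' @param tempo_bpm tempo in (dotted-quarter) beats per minute.
#' @param sixteenths_per_beat sixteenths per beat.
#' @return `path`, invisibly.
#' @export
write_midi <- function(stream, path, tempo_bpm = 72,
                       sixteenths_per_beat = 6L) {
  stopifnot(inherits(stream, "note_stream"))
  if (length(stream$onsets_s) && any(stream$onsets_s < 0))
    stop("cannot encode negative onset times in a MIDI file", call. = FALSE)
  us_per_quarter <- round(60e6 * 4 / (tempo_bpm * sixteenths_per_beat))
  sec_per_tick <- us_per_quarter / 1e6 / .TPQ
  # track 0: tempo + end of track
  tr0 <- c(as.raw(0x00), as.raw(c(0xFF, 0x51, 0x03)), .u24(us_per_quarter),
           as.raw(0x00), as.raw(c(0xFF, 0x2F, 0x00)))
  # track 1: interleaved note-on / note-off events in tick order
  ticks_on <- round(stream$onsets_s / sec_per_tick)
  dur_ticks <- max(1L, round(.TPQ / (4 * 2)))  # half a sixteenth
  n <- length(ticks_on)
  if (n) {
    ev <- data.frame(
      tick = c(ticks_on, ticks_on + dur_ticks),
      on = rep(c(TRUE, FALSE), each = n),
      pitch = rep(stream$pitches, 2L),
      vel = c(stream$velocities, rep(0L, n)))
    ev <- ev[order(ev$tick, !ev$on), ]
    delta <- diff(c(0, ev$tick))
    chunks <- lapply(seq_len(nrow(ev)), function(i)
      c(.varint_encode(delta[i]),
        as.raw(c(if (ev$on[i]) 0x90 else 0x80, ev$pitch[i], ev$vel[i]))))
    body <- do.call(c, chunks)
  } else body <- raw(0)
  tr1 <- c(body, as.raw(0x00), as.raw(c(0xFF, 0x2F, 0x00)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), .u32(6L), .u16(1L), .u16(2L), .u16(.TPQ),
             charToRaw("MTrk"), .u32(length(tr0)), tr0,
             charToRaw("MTrk"), .u32(length(tr1)), tr1), con)
  invisible(path)
}

#' Parse a Standard MIDI File into a note stream
#'
#' Supports formats 0 and 1 with metrical time division. Note onsets are
#' the absolute times (seconds) of note-on events with velocity > 0;
#' velocity-0 note-ons are note-offs. Tempo meta events from all tracks
#' form a piecewise tempo map (default 120 QPM before the first event).
#'
#' @param file path to a `.mid` file.
#' @param performer_id label for the returned stream (default: file name).
#' @return a [note_stream()].
#' @export
parse_midi <- function(file, performer_id = basename(file)) {
  bytes <- readBin(file, "raw", file.size(file))
  pos <- 1L
  fail <- function(msg) stop(sprintf("MIDI parse error at byte %d: %s",
                                     pos - 1L, msg), call. = FALSE)
  need <- function(k) if (pos + k - 1L > length(bytes)) fail("truncated file")
  rd_u <- function(k) {
    need(k)
    v <- sum(as.integer(bytes[pos:(pos + k - 1L)]) * 256^((k - 1L):0))
    pos <<- pos + k
    v
  }
  rd_varint <- function() {
    v <- 0
    repeat {
      need(1L)
      b <- as.integer(bytes[pos]); pos <<- pos + 1L
      v <- v * 128 + (b %% 128L)
      if (b < 128L) return(v)
    }
  }
  need(4L)
  if (rawToChar(bytes[1:4]) != "MThd") fail("missing MThd header")
  pos <- 5L
  if (rd_u(4L) != 6L) fail("unexpected MThd length")
  fmt <- rd_u(2L)
  if (!fmt %in% c(0L, 1L)) fail(sprintf("unsupported format %d", fmt))
  ntrk <- rd_u(2L)
  division <- rd_u(2L)
  if (division >= 32768L) fail("SMPTE time division not supported")
  notes <- list(); tempos <- list()
  for (trk in seq_len(ntrk)) {
    need(4L)
    if (rawToChar(bytes[pos:(pos + 3L)]) != "MTrk") fail("missing MTrk")
    pos <- pos + 4L
    trk_len <- rd_u(4L)
    trk_end <- pos + trk_len
    tick <- 0
    status <- NA_integer_
    while (pos < trk_end) {
      tick <- tick + rd_varint()
      need(1L)
      b <- as.integer(bytes[pos])
      if (b >= 128L) { status <- b; pos <- pos + 1L } else if (is.na(status))
        fail("data byte without running status")
      hi <- status %/% 16L
      if (status == 255L) {                       # meta event
        type <- rd_u(1L)
        len <- rd_varint()
        if (type == 0x51 && len == 3L) {
          tempos[[length(tempos) + 1L]] <- c(tick, rd_u(3L))
        } else {
          need(len); pos <- pos + len
        }
        if (type == 0x2F) break
        status <- NA_integer_
      } else if (status %in% c(240L, 247L)) {     # sysex
        len <- rd_varint(); need(len); pos <- pos + len
        status <- NA_integer_
      } else if (hi %in% c(12L, 13L)) {           # 1 data byte
        pos <- pos + 1L
      } else {                                    # 2 data bytes
        need(2L)
        d1 <- as.integer(bytes[pos]); d2 <- as.integer(bytes[pos + 1L])
        pos <- pos + 2L
        if (hi == 9L && d2 > 0L)
          notes[[length(notes) + 1L]] <- c(tick, d1, d2)
      }
    }
    pos <- trk_end
  }
  if (!length(notes))
    return(note_stream(numeric(0), integer(0), integer(0), performer_id))
  nm <- do.call(rbind, notes)
  tm <- if (length(tempos)) do.call(rbind, tempos) else
    matrix(c(0, 500000), 1L)
  tm <- tm[order(tm[, 1]), , drop = FALSE]
  if (tm[1, 1] > 0) tm <- rbind(c(0, 500000), tm)
  # piecewise-linear tick -> seconds map
  tick_nodes <- tm[, 1]
  sec_nodes <- cumsum(c(0, diff(tick_nodes) * tm[-nrow(tm), 2] / 1e6 / division))
  tick2sec <- function(tk) {
    k <- findInterval(tk, tick_nodes)
    sec_nodes[k] + (tk - tick_nodes[k]) * tm[k, 2] / 1e6 / division
  }
  ord <- order(nm[, 1])
  on_s <- tick2sec(nm[ord, 1])
  note_stream(.force_increasing(on_s, eps = 1e-9),
              pitches = as.integer(nm[ord, 2]),
              velocities = as.integer(nm[ord, 3]),
              performer_id = performer_id)
}
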