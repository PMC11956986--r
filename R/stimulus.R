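#' Stimulus specification for the beat-ambiguous auditory sequence
#'
#' Bundles every synthesis constant of the 36-s amplitude-modulated tone used
#' in the beat-imagery task: a 333.3 Hz pure-tone carrier, amplitude-modulated
#' at 2.4 Hz with an asymmetric Hanning envelope (22 ms rise, 394 ms fall,
#' modulation between 0 and 1), further modulated by an 11 Hz sinusoid, with a
#' 3-s extension copied from the waveform and an 880 Hz / 40 ms probe tone
#' placed on a binary (34.184 s) or ternary (33.732 s) beat.
#'
#' @param carrier_hz carrier frequency (Hz).
#' @param am_rate_hz amplitude-modulation (beat) rate (Hz).
#' @param rise_ms,fall_ms rise/fall time of the asymmetric Hanning AM cycle (ms).
#'   Their sum must fit in one AM period.
#' @param mod2_hz frequency of the secondary sinusoidal modulator (Hz).
#' @param mod2_depth depth of the secondary modulator in `[0, 1]`.
#' @param base_duration_s duration of the original stimulus (s).
#' @param extension_s duration copied from the waveform and appended (s).
#' @param probe_hz,probe_dur_ms probe-tone frequency (Hz) and duration (ms).
#' @param probe_onset_binary_s,probe_onset_ternary_s probe onsets (s from
#'   trial start) for the binary and ternary beat positions.
#' @param probe_ramp_ms raised-cosine on/off ramp applied to the probe (ms).
#' @param probe_gain linear gain of the probe tone relative to full scale.
#' @param extension_source which part of the modulated waveform the appended
#'   extension copies: `"start"` (default) or `"end"`.
#' @param fs sampling rate (Hz).
#' @return An object of class `stimulus_spec` (a validated list).
#' @export
stimulus_spec <- function(carrier_hz = 333.3, am_rate_hz = 2.4,
                          rise_ms = 22, fall_ms = 394,
                          mod2_hz = 11, mod2_depth = 0.5,
                          base_duration_s = 33, extension_s = 3,
                          probe_hz = 880, probe_dur_ms = 40,
                          probe_onset_binary_s = 34.184,
                          probe_onset_ternary_s = 33.732,
                          probe_ramp_ms = 5, probe_gain = 0.5,
                          extension_source = c("start", "end"),
                          fs = 44100) {
  extension_source <- match.arg(extension_source)
  spec <- list(carrier_hz = carrier_hz, am_rate_hz = am_rate_hz,
               rise_ms = rise_ms, fall_ms = fall_ms,
               mod2_hz = mod2_hz, mod2_depth = mod2_depth,
               base_duration_s = base_duration_s, extension_s = extension_s,
               probe_hz = probe_hz, probe_dur_ms = probe_dur_ms,
               probe_onset_binary_s = probe_onset_binary_s,
               probe_onset_ternary_s = probe_onset_ternary_s,
               probe_ramp_ms = probe_ramp_ms, probe_gain = probe_gain,
               extension_source = extension_source, fs = fs)
  validate_stimulus_spec(spec)
  class(spec) <- "stimulus_spec"
  spec
}

validate_stimulus_spec <- function(spec) {
  pos <- c("carrier_hz", "am_rate_hz", "rise_ms", "fall_ms", "mod2_hz",
           "base_duration_s", "extension_s", "probe_hz", "probe_dur_ms", "fs")
  for (f in pos) {
    if (!is.numeric(spec[[f]]) || length(spec[[f]]) != 1L || spec[[f]] <= 0)
      stop("stimulus spec: '", f, "' must be a positive scalar", call. = FALSE)
  }
  if (spec$mod2_depth < 0 || spec$mod2_depth > 1)
    stop("stimulus spec: mod2_depth must lie in [0, 1]", call. = FALSE)
  if (spec$rise_ms + spec$fall_ms > 1000 / spec$am_rate_hz)
    stop("stimulus spec: rise_ms + fall_ms exceeds one AM period (",
         round(1000 / spec$am_rate_hz, 3), " ms)", call. = FALSE)
  total <- spec$base_duration_s + spec$extension_s
  if (spec$probe_onset_binary_s >= total || spec$probe_onset_ternary_s >= total)
    stop("stimulus spec: probe onsets must fall before the end of the stimulus",
         call. = FALSE)
  invisible(spec)
}

#' Asymmetric Hanning amplitude envelope
#'
#' One envelope cycle is a half-raised-cosine rise (0 to 1 over `rise_ms`)
#' immediately followed by a half-raised-cosine fall (1 to 0 over `fall_ms`),
#' zero-padded to the full AM period `1/am_rate_hz` so the modulation rate is
#' exactly the beat rate, then tiled for the requested duration.
#'
#' @param spec a [stimulus_spec()].
#' @param duration_s duration of envelope to generate (s).
#' @return A `waveform` list with elements `samples` (values in `[0, 1]`) and
#'   `fs`.
#' @export
build_envelope <- function(spec, duration_s) {
  validate_stimulus_spec(spec)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive", call. = FALSE)
  fs <- spec$fs
  period_n <- round(fs / spec$am_rate_hz)
  rise_n <- round(spec$rise_ms / 1000 * fs)
  fall_n <- round(spec$fall_ms / 1000 * fs)
  if (rise_n + fall_n > period_n)
    stop("envelope rise + fall exceeds the AM period at this sampling rate",
         call. = FALSE)
  # half-raised-cosine up, then down; peak value 1 at the junction
  up <- if (rise_n > 0) 0.5 - 0.5 * cos(pi * seq(0, rise_n - 1) / rise_n) else numeric(0)
  down <- if (fall_n > 0) 0.5 + 0.5 * cos(pi * seq(1, fall_n) / fall_n) else numeric(0)
  cycle <- c(up, 1, down)
  cycle <- c(cycle, numeric(max(0L, period_n - length(cycle))))[seq_len(period_n)]
  n <- round(duration_s * fs)
  env <- rep_len(cycle, n)
  waveform(env, fs)
}

waveform <- function(samples, fs) {
  structure(list(samples = as.numeric(samples), fs = fs), class = "waveform")
}

#' Synthesize the beat-ambiguous auditory stimulus
#'
#' Multiplies the pure-tone carrier by the tiled asymmetric Hanning envelope
#' and by a normalized secondary modulator `(1 + m sin(2 pi f2 t)) / (1 + m)`,
#' then appends a verbatim copy of `extension_s` seconds of the modulated
#' waveform (from its start by default) so a probe can be placed beyond the
#' original duration.
#'
#' @param spec a [stimulus_spec()].
#' @return A `waveform` of duration `base_duration_s + extension_s`.
#' @export
synthesize_stimulus <- function(spec) {
  validate_stimulus_spec(spec)
  if (spec$fs < 2 * spec$carrier_hz)
    stop("sampling rate below twice the carrier frequency: aliasing", call. = FALSE)
  fs <- spec$fs
  n_base <- round(spec$base_duration_s * fs)
  t <- seq_len(n_base - 1 + 1) - 1
  t <- t / fs
  env <- build_envelope(spec, spec$base_duration_s)$samples
  carrier <- sin(2 * pi * spec$carrier_hz * t)
  m <- spec$mod2_depth
  mod2 <- (1 + m * sin(2 * pi * spec$mod2_hz * t)) / (1 + m)
  x <- carrier * env * mod2
  n_ext <- round(spec$extension_s * fs)
  ext <- if (spec$extension_source == "start") x[seq_len(n_ext)]
         else x[seq.int(n_base - n_ext + 1L, n_base)]
  waveform(c(x, ext), fs)
}

#' Add the probe tone to a stimulus waveform
#'
#' Sums an 880 Hz tone burst of `probe_dur_ms` at gain `probe_gain` onto the
#' waveform at the binary (34.184 s) or ternary (33.732 s) beat position. A
#' short raised-cosine onset/offset ramp (default 5 ms) avoids broadband
#' clicks. The result is rescaled (globally) only if any mixed sample would
#' exceed full scale; otherwise every sample outside the probe window is
#' bit-identical to the input.
#'
#' @param wave a `waveform` (from [synthesize_stimulus()]).
#' @param spec the [stimulus_spec()] used to build it.
#' @param probe_type `"binary"` or `"ternary"`.
#' @return A `waveform` with the probe summed in; samples within `[-1, 1]`.
#' @export
add_probe <- function(wave, spec, probe_type = c("binary", "ternary")) {
  probe_type <- match.arg(probe_type)
  validate_stimulus_spec(spec)
  fs <- wave$fs
  onset_s <- switch(probe_type,
                    binary = spec$probe_onset_binary_s,
                    ternary = spec$probe_onset_ternary_s)
  ramp_n <- round(spec$probe_ramp_ms / 1000 * fs)
  dur_n <- round((spec$probe_dur_ms + 2 * spec$probe_ramp_ms) / 1000 * fs)
  start <- round(onset_s * fs) + 1L
  if (start + dur_n - 1L > length(wave$samples))
    stop("probe extends past the end of the waveform", call. = FALSE)
  tt <- (seq_len(dur_n) - 1) / fs
  burst <- spec$probe_gain * sin(2 * pi * spec$probe_hz * tt)
  if (ramp_n > 0) {
    ramp <- 0.5 - 0.5 * cos(pi * seq(0, ramp_n - 1) / ramp_n)
    burst[seq_len(ramp_n)] <- burst[seq_len(ramp_n)] * ramp
    burst[seq.int(dur_n - ramp_n + 1L, dur_n)] <-
      burst[seq.int(dur_n - ramp_n + 1L, dur_n)] * rev(ramp)
  }
  out <- wave$samples
  idx <- seq.int(start, start + dur_n - 1L)
  out[idx] <- out[idx] + burst
  peak <- max(abs(out))
  if (peak > 1) out <- out / peak
  waveform(out, fs)
}

#' Write a waveform as a 32-bit float WAV file
#'
#' Minimal RIFF/WAVE writer (format tag 3, IEEE float, mono). Counterpart
#' reader [read_wav()] is provided for round-trip checks.
#'
#' @param wave a `waveform`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(wave$samples)
  data_bytes <- n * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")            # IEEE float
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(wave$fs), con, size = 4, endian = "little")
  writeBin(as.integer(wave$fs * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(wave$samples, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a 32-bit float mono WAV file written by [write_wav()]
#' @param path file path.
#' @return A `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file", call. = FALSE)
  fs <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8))
      if (fmt[1] != 3L) stop("only float32 WAV supported", call. = FALSE)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  waveform(samples, fs)
}
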