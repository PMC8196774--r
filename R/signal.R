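#' Device output profile
#'
#' The acoustic calibration of one smartphone/earphone assembly: for each
#' channel and test frequency, the sound pressure level a full-scale digital
#' sine produces, as measured with a 2-cc coupler.  All amplitude computations
#' are referenced to these full-scale values.
#'
#' @param device Device name present in `table` (default `"iPhone XR"`).
#' @param table A `device_output_table` from [read_device_output_table()].
#' @return An object of class `device_profile`.
#' @export
device_profile <- function(device = "iPhone XR",
                           table = read_device_output_table()) {
  sub <- table[table$device == device, , drop = FALSE]
  if (!nrow(sub))
    stop("no device named '", device, "' in the output table", call. = FALSE)
  if (any(sub$max_output_spl < 60 | sub$max_output_spl > 130))
    stop("max output outside the plausible [60, 130] dB SPL band",
         call. = FALSE)
  for (ch in unique(sub$channel))
    if (!setequal(sub$freq_hz[sub$channel == ch], TEST_FREQUENCIES))
      stop("profile must cover all six frequencies per channel", call. = FALSE)
  structure(list(device = device, table = sub), class = "device_profile")
}

profile_max <- function(profile, freq, channel) {
  stopifnot(inherits(profile, "device_profile"))
  hit <- profile$table$channel == channel &
    profile$table$freq_hz == as.integer(freq)
  if (!any(hit))
    stop("profile has no entry for channel=", channel, ", freq=", freq,
         call. = FALSE)
  profile$table$max_output_spl[which(hit)[1L]]
}

#' Full-scale fraction producing a target SPL
#'
#' Digital amplitude is linear in pressure, so a sine at fraction `a` of full
#' scale produces `max_output + 20*log10(a)` dB SPL; inverting gives
#' `a = 10^((target - max_output)/20)`.  Targets above the device maximum are
#' out of range — this limit is what caps the testable dB HL range.
#'
#' @param target Target level, dB SPL (numeric or [level_spl()]).
#' @param freq Test frequency, Hz.
#' @param channel `"L"` or `"R"`.
#' @param profile A [device_profile()].
#' @return Full-scale amplitude fraction in (0, 1\].
#' @examples
#' xr <- device_profile("iPhone XR")
#' amplitude_for_spl(107.2, 1000, "L", xr)  # 1.0
#' amplitude_for_spl(87.2, 1000, "L", xr)   # 0.1
#' @export
amplitude_for_spl <- function(target, freq, channel, profile) {
  target <- as.numeric(target)
  mx <- profile_max(profile, freq, channel)
  if (target > mx)
    stop("target ", target, " dB SPL exceeds device maximum ", mx,
         " dB SPL at ", freq, " Hz (channel ", channel, ")", call. = FALSE)
  10^((target - mx) / 20)
}

#' Specify a pure-tone stimulus
#'
#' Test tones are rendered as continuous sinusoids (continuous presentation
#' minimizes harmonic distortion and does not demand sustained attention);
#' short raised-cosine ramps at onset and offset avoid spectral splatter.
#'
#' @param freq Tone frequency, Hz; must be below Nyquist.
#' @param level Target level, dB SPL.
#' @param channel `"L"` or `"R"`.
#' @param duration Duration in seconds (default 1; continuous tones are
#'   rendered in renewable blocks of this length).
#' @param sample_rate Sampling rate, Hz (default 44100).
#' @param ramp Raised-cosine ramp duration, s (default 0.02).
#' @return An object of class `tone_spec`.
#' @export
tone_spec <- function(freq, level, channel = "L", duration = 1,
                      sample_rate = 44100, ramp = 0.02) {
  stopifnot(freq > 0, freq < sample_rate / 2, duration > 0,
            ramp >= 0, 2 * ramp <= duration)
  structure(list(freq = freq, level = as.numeric(level), channel = channel,
                 duration = duration, sample_rate = sample_rate, ramp = ramp),
            class = "tone_spec")
}

raised_cosine_envelope <- function(n, ramp_samples) {
  env <- rep(1, n)
  if (ramp_samples > 0) {
    r <- 0.5 * (1 - cos(pi * seq_len(ramp_samples) / ramp_samples))
    env[seq_len(ramp_samples)] <- r
    env[n + 1 - seq_len(ramp_samples)] <- rev(r)
  }
  env
}

#' Render a calibrated pure tone
#'
#' @param spec A [tone_spec()].
#' @param profile A [device_profile()] supplying the full-scale reference.
#' @param path Optional path; when given, the buffer is also written as a
#'   16-bit PCM WAV file.
#' @return An `audio_buffer`: list with `samples` (numeric in \[-1, 1\]),
#'   `sample_rate` and the generating spec.
#' @examples
#' buf <- render_tone(tone_spec(1000, 80), device_profile("iPhone XR"))
#' measure_spl(buf, reference = 107.2)
#' @export
render_tone <- function(spec, profile, path = NULL) {
  stopifnot(inherits(spec, "tone_spec"))
  amp <- amplitude_for_spl(spec$level, spec$freq, spec$channel, profile)
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  env <- raised_cosine_envelope(n, round(spec$ramp * spec$sample_rate))
  samples <- amp * env * sin(2 * pi * spec$freq * t)
  buf <- structure(list(samples = samples, sample_rate = spec$sample_rate,
                        spec = spec), class = "audio_buffer")
  if (!is.null(path)) write_wav(buf, path)
  buf
}

#' Render calibrated narrow-band masking noise
#'
#' Masking noise is band-limited Gaussian noise in a one-third-octave band
#' centred on the test frequency (the clinical convention for narrow-band
#' maskers), realized by zeroing all FFT components outside
#' `[center/2^(1/6), center*2^(1/6)]` and scaling the result so its RMS
#' corresponds to the requested SPL under the device profile.
#'
#' @param center Centre frequency, Hz (one of the six test frequencies).
#' @param level Target level, dB SPL.
#' @param channel `"L"` or `"R"`.
#' @param profile A [device_profile()].
#' @param duration Duration in seconds (default 1).
#' @param sample_rate Sampling rate, Hz (default 44100).
#' @param path Optional WAV output path.
#' @return An `audio_buffer`.
#' @export
render_masking_noise <- function(center, level, channel = "L", profile,
                                 duration = 1, sample_rate = 44100,
                                 path = NULL) {
  freq_key(center)
  level <- as.numeric(level)
  amp_target <- amplitude_for_spl(level, center, channel, profile)
  n <- round(duration * sample_rate)
  noise <- stats::rnorm(n)
  spec <- stats::fft(noise)
  f <- (seq_len(n) - 1) / n * sample_rate
  f <- pmin(f, sample_rate - f)             # two-sided frequency axis
  lo <- center / 2^(1 / 6); hi <- center * 2^(1 / 6)
  spec[f < lo | f > hi] <- 0
  band <- Re(stats::fft(spec, inverse = TRUE)) / n
  ## scale so RMS equals that of a sine at the target SPL (amp/sqrt(2))
  band <- band * (amp_target / sqrt(2)) / sqrt(mean(band^2))
  if (max(abs(band)) > 1)
    stop("requested masking level clips at full scale", call. = FALSE)
  buf <- structure(list(samples = band, sample_rate = sample_rate,
                        spec = list(center = center, level = level,
                                    channel = channel)),
                   class = "audio_buffer")
  if (!is.null(path)) write_wav(buf, path)
  buf
}

#' Measure the sound pressure level of a buffer
#'
#' Unweighted RMS level referenced to the device's full-scale calibration:
#' `SPL = 20*log10(RMS) + reference`, where `reference` is the SPL of a
#' full-scale (RMS = 1) signal.  A full-scale sine therefore reads 3.01 dB
#' below the reference.  Digital silence returns `-Inf` ("below floor").
#'
#' @param buffer An `audio_buffer`, or a numeric sample vector.
#' @param reference Full-scale reference, dB SPL (e.g. the profile's max
#'   output at the tone frequency).
#' @param block Optional block length in seconds; when given, the maximum RMS
#'   over consecutive blocks is used (ambient monitoring, default 0.25 s
#'   blocks when `block = TRUE`).
#' @param trim Seconds to drop from each end before measuring (use the ramp
#'   duration to meter the steady state only; default 0).
#' @return A [level_spl()], or `-Inf` for silence.
#' @export
measure_spl <- function(buffer, reference, block = NULL, trim = 0) {
  samples <- if (inherits(buffer, "audio_buffer")) buffer$samples
             else as.numeric(buffer)
  if (!length(samples)) stop("empty buffer", call. = FALSE)
  sr <- if (inherits(buffer, "audio_buffer")) buffer$sample_rate else 44100
  if (trim > 0) {
    k <- round(trim * sr)
    if (2 * k >= length(samples)) stop("trim longer than buffer", call. = FALSE)
    samples <- samples[(k + 1):(length(samples) - k)]
  }
  if (isTRUE(block)) block <- 0.25
  rms <- if (is.numeric(block) && block > 0) {
    bs <- max(1L, round(block * sr))
    starts <- seq(1L, length(samples), by = bs)
    max(vapply(starts, function(s)
      sqrt(mean(samples[s:min(s + bs - 1L, length(samples))]^2)), 0))
  } else sqrt(mean(samples^2))
  if (rms == 0) return(-Inf)
  level_spl(20 * log10(rms) + reference)
}

#' Meter a buffer against a device profile
#'
#' The coupler-measured maxima in a [device_profile()] are the SPLs of a
#' *full-scale sine*, whose RMS is 3.01 dB below full scale; a
#' profile-referenced meter therefore reads
#' `20*log10(RMS * sqrt(2)) + max_output`.  Rendering a tone at a target SPL
#' and metering it with this function returns the target (within the ramp
#' contribution; pass `trim` to meter the steady state only).
#'
#' @inheritParams measure_spl
#' @param freq,channel Profile cell supplying the full-scale reference.
#' @param profile A [device_profile()].
#' @return A [level_spl()], or `-Inf` for silence.
#' @examples
#' xr <- device_profile("iPhone XR")
#' buf <- render_tone(tone_spec(1000, 80), xr)
#' measure_spl_profile(buf, 1000, "L", xr, trim = 0.02)  # ~80 dB SPL
#' @export
measure_spl_profile <- function(buffer, freq, channel, profile, block = NULL,
                                trim = 0) {
  mx <- profile_max(profile, freq, channel)
  measure_spl(buffer, reference = mx + 20 * log10(sqrt(2)), block = block,
              trim = trim)
}

## ---- WAV I/O ---------------------------------------------------------------
## Minimal 16-bit PCM RIFF reader/writer (mono or per-channel buffers).

#' Write and read 16-bit PCM WAV files
#'
#' @param buffer An `audio_buffer` or numeric vector of samples in \[-1, 1\].
#' @param path File path.
#' @param sample_rate Sampling rate when `buffer` is a bare vector.
#' @return `read_wav()`: an `audio_buffer`.
#' @export
write_wav <- function(buffer, path, sample_rate = 44100) {
  samples <- if (inherits(buffer, "audio_buffer")) buffer$samples
             else as.numeric(buffer)
  if (inherits(buffer, "audio_buffer")) sample_rate <- buffer$sample_rate
  pcm <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
  con <- file(path, "wb"); on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 4); stopifnot(identical(hdr, "RIFF"))
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  stopifnot(identical(readChar(con, 4), "WAVE"))
  sample_rate <- NA_integer_; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", size - 8))
      stopifnot(fmt[1] == 1L, fmt[2] == 1L)
    } else if (id == "data") {
      samples <- readBin(con, "integer", size / 2, size = 2,
                         endian = "little") / 32767
      break
    } else invisible(readBin(con, "raw", size))
  }
  stopifnot(!is.null(samples))
  structure(list(samples = samples, sample_rate = sample_rate, spec = NULL),
            class = "audio_buffer")
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat("Audio buffer:", length(x$samples), "samples @", x$sample_rate, "Hz (",
      round(length(x$samples) / x$sample_rate, 3), "s )\n")
  invisible(x)
}
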