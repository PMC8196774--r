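#' Masking parameters
#'
#' Interaural attenuation (IA) is the number of dB an air-conducted signal
#' loses crossing (chiefly by bone conduction) from the test ear to the
#' non-test ear; the minimum clinical assumption is 40 dB.  When a
#' presentation exceeds the IA, the excess can reach the opposite cochlea and
#' narrow-band masking noise at least that loud is needed in the non-test ear.
#'
#' @param interaural_attenuation IA in dB (default 40).
#' @param enabled Whether the session engine applies masking (default `FALSE`,
#'   appropriate for normal-hearing testing; the level is reported either way).
#' @return An object of class `masking_params`.
#' @export
masking_params <- function(interaural_attenuation = 40, enabled = FALSE) {
  stopifnot(interaural_attenuation > 0)
  structure(list(interaural_attenuation = interaural_attenuation,
                 enabled = isTRUE(enabled)),
            class = "masking_params")
}

#' Minimum masking-noise level for the non-test ear
#'
#' A tone at `presentation` dB SPL in the test ear may arrive at the non-test
#' ear attenuated by the IA; masking noise at least `presentation - IA` dB SPL
#' is then required there.  When the crossover margin is zero or negative no
#' masking is needed and `NULL` is returned.
#'
#' @param presentation Test-ear presentation level, dB SPL.
#' @param params A [masking_params()].
#' @return A [level_spl()], or `NULL` when no masking is needed.
#' @examples
#' masking_level(60, masking_params(40))  # 20 dB SPL
#' masking_level(40, masking_params(40))  # NULL
#' @export
masking_level <- function(presentation, params = masking_params()) {
  stopifnot(is.finite(as.numeric(presentation)))
  need <- as.numeric(presentation) - params$interaural_attenuation
  if (need > 0) level_spl(need) else NULL
}

#' Ambient-noise pause rule
#'
#' The application monitors surrounding noise and pauses the test when the
#' ambient level rises strictly above the configured threshold (default
#' 40 dB SPL).
#'
#' @param ambient_level Measured ambient level, dB SPL.
#' @param config A [session_config()] (only its `noise_pause_threshold` is
#'   used).
#' @return Logical: `TRUE` iff the test should pause.
#' @examples
#' should_pause(45)  # TRUE
#' should_pause(40)  # FALSE: strictly greater than
#' @export
should_pause <- function(ambient_level, config = session_config()) {
  stopifnot(is.finite(as.numeric(ambient_level)))
  as.numeric(ambient_level) > config$noise_pause_threshold
}

#' Configuration of a full test session
#'
#' @param frequencies Ordered test frequencies, Hz; subset of the six
#'   supported (default all six ascending).
#' @param ear_order Character vector ordering the ears (default right, then
#'   left).
#' @param noise_pause_threshold Ambient level above which the test pauses,
#'   dB SPL (default 40).
#' @param retspl_table [retspl_table()] used to report presentation SPLs and
#'   masking levels (default the calibrated HearTest v2 profile).
#' @param masking A [masking_params()].
#' @param staircase Baseline [staircase_config()]; the per-frequency ceiling is
#'   overridden by [max_level_hl()] cell by cell.
#' @return An object of class `session_config`.
#' @export
session_config <- function(frequencies = test_frequencies(),
                           ear_order = c("right", "left"),
                           noise_pause_threshold = 40,
                           retspl_table = packaged_retspl("HearTest v2"),
                           masking = masking_params(),
                           staircase = staircase_config()) {
  stopifnot(all(frequencies %in% TEST_FREQUENCIES),
            !anyDuplicated(frequencies),
            all(ear_order %in% c("right", "left")),
            noise_pause_threshold > 0,
            inherits(retspl_table, "retspl_table"),
            inherits(masking, "masking_params"),
            inherits(staircase, "staircase_config"))
  structure(list(frequencies = as.integer(frequencies), ear_order = ear_order,
                 noise_pause_threshold = noise_pause_threshold,
                 retspl_table = retspl_table, masking = masking,
                 staircase = staircase),
            class = "session_config")
}

#' Run a complete two-ear pure-tone test session
#'
#' Runs one adaptive staircase per ear and frequency in the configured order
#' (each with its own per-frequency ceiling), optionally checks an ambient
#' noise monitor between presentations, and assembles the results into an
#' [audiogram] object with ASHA severity categories.
#'
#' @param listener A [virtual_listener()], or a recorded session transcript
#'   (data frame with columns `ear`, `freq_hz`, `level_dbhl`, `heard`) to
#'   replay.
#' @param config A [session_config()].
#' @param seed Optional integer seed for reproducible stochastic listeners.
#' @param ambient_monitor Optional function of no arguments returning the
#'   current ambient level in dB SPL; consulted before each presentation.
#'   Pauses annotate the session metadata and never discard responses.
#' @return An `audiogram` object.
#' @examples
#' vl <- virtual_listener(rep(10, 6))
#' ag <- run_session(vl)
#' ag
#' @export
run_session <- function(listener, config = session_config(), seed = NULL,
                        ambient_monitor = NULL) {
  stopifnot(inherits(config, "session_config"))
  if (!is.null(seed)) set.seed(seed)
  replaying <- is.data.frame(listener)
  if (!replaying) stopifnot(inherits(listener, "virtual_listener"))

  cells <- list(); transcripts <- list(); pauses <- list()
  for (ear in config$ear_order) {
    for (freq in config$frequencies) {
      cfg <- config$staircase
      cfg$ceiling <- max_level_hl(freq)
      if (replaying) {
        sub <- listener[listener$ear == ear & listener$freq_hz == freq, ,
                        drop = FALSE]
        state <- replay_track(sub[, c("level_dbhl", "heard")], cfg)
        if (!is_terminal(state))
          stop("transcript for ear=", ear, " freq=", freq,
               " ends before the track terminates", call. = FALSE)
        res <- list(threshold = state$threshold, history = state$history)
      } else {
        respond_at <- response_fn(listener, ear, freq)
        wrapped <- if (is.null(ambient_monitor)) respond_at else {
          function(level) {
            amb <- ambient_monitor()
            if (should_pause(amb, config))
              pauses[[length(pauses) + 1L]] <<- list(ear = ear, freq_hz = freq,
                                                     ambient_spl = amb)
            respond_at(level)
          }
        }
        res <- run_track(wrapped, cfg)
      }
      thr <- res$threshold
      nr <- is_no_response(thr)
      cells[[length(cells) + 1L]] <- data.frame(
        ear = ear, freq_hz = freq,
        threshold_dbhl = if (nr) NA_real_ else as.numeric(thr),
        no_response = nr,
        category = if (nr) NA_character_ else
          classify_threshold(as.numeric(thr)),
        stringsAsFactors = FALSE)
      transcripts[[paste(ear, freq, sep = "_")]] <- res$history
    }
  }
  new_audiogram(do.call(rbind, cells), config = config,
                listener_id = if (replaying) "transcript" else listener$id,
                transcripts = transcripts, pauses = pauses)
}

## ---- audiogram object ------------------------------------------------------

#' Audiogram objects
#'
#' An audiogram holds per-ear, per-frequency hearing thresholds in dB HL, a
#' `no_response` flag for cells where the listener never responded at the
#' device ceiling, and the ASHA severity category of each measured threshold.
#' Created by [run_session()]; methods: `print`, `summary`, `plot` (clinical
#' orientation: log frequency axis, inverted dB HL axis, O/X right-left
#' symbols) and `as.data.frame`.
#'
#' @param x,object An `audiogram`.
#' @param ... Unused.
#' @name audiogram
NULL

new_audiogram <- function(results, config, listener_id = NULL,
                          transcripts = NULL, pauses = NULL) {
  stopifnot(!anyDuplicated(results[, c("ear", "freq_hz")]))
  structure(list(results = results, config = config,
                 listener_id = listener_id, transcripts = transcripts,
                 pauses = pauses, created = format(Sys.time(), tz = "UTC")),
            class = "audiogram")
}

#' @rdname audiogram
#' @export
print.audiogram <- function(x, ...) {
  cat("Pure-tone audiogram",
      if (!is.null(x$listener_id)) paste0("(", x$listener_id, ")"), "\n")
  df <- x$results
  df$threshold <- ifelse(df$no_response, "NR",
                         vapply(df$threshold_dbhl, format_num, ""))
  wide <- stats::reshape(df[, c("ear", "freq_hz", "threshold")],
                         idvar = "ear", timevar = "freq_hz",
                         direction = "wide")
  names(wide) <- sub("^threshold\\.", "", names(wide))
  print(wide, row.names = FALSE)
  if (length(x$pauses))
    cat("(", length(x$pauses), "ambient-noise pause events )\n")
  invisible(x)
}

#' @rdname audiogram
#' @export
summary.audiogram <- function(object, ...) {
  df <- object$results
  cat("Thresholds (dB HL) and ASHA categories\n")
  print(df[, c("ear", "freq_hz", "threshold_dbhl", "no_response", "category")],
        row.names = FALSE)
  measured <- df$threshold_dbhl[!df$no_response]
  if (length(measured))
    cat("\nWorst measured threshold:", max(measured), "dB HL (",
        classify_threshold(max(measured)), ")\n")
  if (any(df$no_response))
    cat(sum(df$no_response), "cell(s) with no response at ceiling\n")
  invisible(df)
}

#' @rdname audiogram
#' @export
as.data.frame.audiogram <- function(x, ...) x$results

#' @rdname audiogram
#' @export
plot.audiogram <- function(x, ...) {
  df <- x$results
  freqs <- sort(unique(df$freq_hz))
  graphics::plot(NA, xlim = range(log2(freqs)), ylim = c(120, -10),
                 xaxt = "n", xlab = "Frequency (Hz)",
                 ylab = "Hearing level (dB HL)",
                 main = "Audiogram", ...)
  graphics::axis(1, at = log2(freqs), labels = freqs)
  graphics::abline(h = c(25, 40, 55, 70, 90), col = "grey85", lty = 3)
  for (ear in unique(df$ear)) {
    sub <- df[df$ear == ear & !df$no_response, ]
    sub <- sub[order(sub$freq_hz), ]
    col <- if (ear == "right") "red" else "blue"
    pch <- if (ear == "right") 1 else 4    # O right, X left
    graphics::lines(log2(sub$freq_hz), sub$threshold_dbhl, col = col)
    graphics::points(log2(sub$freq_hz), sub$threshold_dbhl, col = col,
                     pch = pch, cex = 1.3)
    nr <- df[df$ear == ear & df$no_response, ]
    if (nrow(nr))
      graphics::points(log2(nr$freq_hz),
                       vapply(nr$freq_hz, max_level_hl, 0),
                       col = col, pch = 6)  # down triangle at ceiling
  }
  invisible(x)
}

#' Serialize audiograms
#'
#' `write_audiogram()` writes a structured JSON document (per-ear arrays of
#' frequency, threshold, no-response flag and category, plus pause-event
#' metadata); `write_audiogram_table()` writes the flat delimited form.
#' `read_audiogram()` restores the JSON form to an `audiogram` object.
#'
#' @param audiogram An [audiogram] object.
#' @param path File path.
#' @return `read_audiogram()`: an `audiogram` object.
#' @export
write_audiogram <- function(audiogram, path) {
  df <- audiogram$results
  ears <- lapply(split(df, df$ear), function(sub)
    lapply(seq_len(nrow(sub)), function(i) list(
      freq_hz = sub$freq_hz[i],
      threshold_dbhl = if (sub$no_response[i]) NULL else sub$threshold_dbhl[i],
      no_response = sub$no_response[i],
      category = if (sub$no_response[i]) NULL else sub$category[i])))
  ## `created` is deliberately omitted so deterministic reruns are byte-identical
  doc <- list(listener_id = audiogram$listener_id,
              noise_pause_threshold_spl =
                audiogram$config$noise_pause_threshold,
              pause_events = length(audiogram$pauses),
              ears = ears)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_audiogram
#' @export
write_audiogram_table <- function(audiogram, path) {
  utils::write.csv(audiogram$results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_audiogram
#' @export
read_audiogram <- function(path) {
  doc <- jsonlite::read_json(path)
  rows <- list()
  for (ear in names(doc$ears)) {
    for (cell in doc$ears[[ear]]) {
      nr <- isTRUE(cell$no_response)
      rows[[length(rows) + 1L]] <- data.frame(
        ear = ear, freq_hz = as.integer(cell$freq_hz),
        threshold_dbhl = if (nr) NA_real_ else as.numeric(cell$threshold_dbhl),
        no_response = nr,
        category = if (nr) NA_character_ else cell$category,
        stringsAsFactors = FALSE)
    }
  }
  new_audiogram(do.call(rbind, rows), config = session_config(),
                listener_id = doc$listener_id)
}
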