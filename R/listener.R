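#' Construct a virtual listener
#'
#' A virtual listener stands in for a human subject: per-ear, per-frequency
#' true hearing thresholds plus a psychometric response model mapping a
#' presentation level to the probability of pressing "I can hear it".
#'
#' Two response models are supported.  `"deterministic_step"` responds iff the
#' level is at or above the true threshold.  `"logistic"` responds with
#' probability `guess + (1 - guess - lapse) * plogis((level - threshold) /
#' slope)`: `slope` is the logistic scale in dB (smaller = steeper), `guess`
#' the rate of spurious responses far below threshold, `lapse` the rate of
#' missed responses far above it (the "unsure -> I can't hear it" behaviour).
#' The default scale of 0.5 dB (steepness 2 per dB) models an attentive
#' listener: steep enough for the 5 dB staircase grid to recover thresholds
#' tightly, while guess and lapse still exercise every stochastic path.
#'
#' @param thresholds True thresholds in dB HL: either a named numeric vector
#'   over the six test frequencies (applied to both ears) or a data frame with
#'   columns `ear` ("left"/"right"), `freq_hz`, `threshold_dbhl`.
#' @param model `"deterministic_step"` or `"logistic"`.
#' @param slope Logistic scale parameter, dB (default 0.5).
#' @param guess_rate,lapse_rate Probabilities in \[0, 0.1\] (default 0.01 each
#'   for the logistic model, 0 for the step model).
#' @param id Optional listener identifier.
#' @return An object of class `virtual_listener`.
#' @examples
#' vl <- virtual_listener(rep(10, 6))
#' respond(vl, "right", 1000, level = 15)  # TRUE: 15 >= 10
#' @export
virtual_listener <- function(thresholds, model = c("deterministic_step", "logistic"),
                             slope = 0.5, guess_rate = NULL, lapse_rate = NULL,
                             id = "listener") {
  model <- match.arg(model)
  if (is.null(guess_rate)) guess_rate <- if (model == "logistic") 0.01 else 0
  if (is.null(lapse_rate)) lapse_rate <- if (model == "logistic") 0.01 else 0
  stopifnot(slope > 0, guess_rate >= 0, guess_rate <= 0.1,
            lapse_rate >= 0, lapse_rate <= 0.1)
  if (is.data.frame(thresholds)) {
    stopifnot(all(c("ear", "freq_hz", "threshold_dbhl") %in% names(thresholds)))
    thr <- thresholds
  } else {
    thresholds <- as.numeric(thresholds)
    if (length(thresholds) != length(TEST_FREQUENCIES))
      stop("need one threshold per test frequency", call. = FALSE)
    thr <- data.frame(ear = rep(c("right", "left"),
                                each = length(TEST_FREQUENCIES)),
                      freq_hz = rep(TEST_FREQUENCIES, 2L),
                      threshold_dbhl = rep(thresholds, 2L))
  }
  if (any(thr$threshold_dbhl < -10 | thr$threshold_dbhl > 120))
    stop("true thresholds must lie in [-10, 120] dB HL", call. = FALSE)
  structure(list(id = id, thresholds = thr, model = model, slope = slope,
                 guess_rate = guess_rate, lapse_rate = lapse_rate),
            class = "virtual_listener")
}

#' @export
print.virtual_listener <- function(x, ...) {
  cat("Virtual listener '", x$id, "' (", x$model, " model)\n", sep = "")
  if (x$model == "logistic")
    cat("  slope", x$slope, "dB | guess", x$guess_rate,
        "| lapse", x$lapse_rate, "\n")
  print(true_thresholds(x))
  invisible(x)
}

#' True thresholds of a virtual listener as an ear-by-frequency matrix
#' @param listener A [virtual_listener()].
#' @return Numeric matrix, rows `right`/`left`, columns the test frequencies.
#' @export
true_thresholds <- function(listener) {
  thr <- listener$thresholds
  ears <- unique(thr$ear)
  m <- matrix(NA_real_, length(ears), length(TEST_FREQUENCIES),
              dimnames = list(ears, as.character(TEST_FREQUENCIES)))
  for (i in seq_len(nrow(thr)))
    m[thr$ear[i], as.character(thr$freq_hz[i])] <- thr$threshold_dbhl[i]
  m
}

listener_threshold <- function(listener, ear, freq) {
  thr <- listener$thresholds
  hit <- thr$ear == ear & thr$freq_hz == as.integer(freq)
  if (!any(hit))
    stop("listener '", listener$id, "' has no threshold at ear=", ear,
         ", freq=", freq, " Hz", call. = FALSE)
  thr$threshold_dbhl[which(hit)[1L]]
}

#' Simulate one button press
#'
#' Draws a single heard/not-heard response at the given presentation level.
#' The step model is deterministic (heard iff `level >= threshold`); the
#' logistic model draws from the psychometric function, so callers seeking
#' reproducibility should set the RNG seed (e.g. via `set.seed()` or the
#' `seed` argument of [run_session()]).
#'
#' @param listener A [virtual_listener()].
#' @param ear `"left"` or `"right"`.
#' @param freq Test frequency, Hz.
#' @param level Presentation level, dB HL.
#' @return Logical: `TRUE` iff heard.
#' @export
respond <- function(listener, ear, freq, level) {
  p <- response_probability(listener, ear, freq, level)
  if (listener$model == "deterministic_step") p >= 1 else stats::runif(1) < p
}

#' Psychometric response probability at a level
#' @inheritParams respond
#' @return Probability in \[0, 1\] of a "heard" response.
#' @export
response_probability <- function(listener, ear, freq, level) {
  thr <- listener_threshold(listener, ear, freq)
  if (listener$model == "deterministic_step")
    return(as.numeric(level >= thr))
  listener$guess_rate + (1 - listener$guess_rate - listener$lapse_rate) *
    stats::plogis((level - thr) / listener$slope)
}

#' Response closure for one ear and frequency
#'
#' Convenience wrapper turning a listener into the `function(level)` expected
#' by [run_track()].
#'
#' @inheritParams respond
#' @return A function of one argument (level, dB HL) returning logical.
#' @export
response_fn <- function(listener, ear, freq) {
  force(listener); force(ear); force(freq)
  function(level) respond(listener, ear, freq, level)
}

## ---- cohorts ---------------------------------------------------------------

#' Specify a simulated cohort
#'
#' Describes a batch of virtual listeners analogous to a recruited
#' normal-hearing group: per-frequency threshold means and standard deviations
#' from which each listener's true thresholds are drawn independently (per ear
#' and frequency), quantized to 1 dB and clamped to \[-10, 120\] dB HL.
#'
#' @param n_listeners Number of listeners (each contributes two ears).
#' @param mean_dbhl Per-frequency mean true threshold, dB HL; scalar or
#'   length-6 vector (default 10, typical of normal hearing).
#' @param sd_dbhl Per-frequency SD, dB; scalar or length-6 (default 5).
#' @param model,slope,guess_rate,lapse_rate Response-model parameters passed to
#'   [virtual_listener()] (logistic scale default 0.5 dB).
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_listeners, mean_dbhl = 10, sd_dbhl = 5,
                        model = "deterministic_step", slope = 0.5,
                        guess_rate = NULL, lapse_rate = NULL, seed = 1L) {
  stopifnot(n_listeners >= 1, all(sd_dbhl >= 0))
  mean_dbhl <- rep_len(as.numeric(mean_dbhl), length(TEST_FREQUENCIES))
  sd_dbhl <- rep_len(as.numeric(sd_dbhl), length(TEST_FREQUENCIES))
  structure(list(n_listeners = as.integer(n_listeners), mean_dbhl = mean_dbhl,
                 sd_dbhl = sd_dbhl, model = model, slope = slope,
                 guess_rate = guess_rate, lapse_rate = lapse_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw a cohort of virtual listeners
#'
#' @param spec A [cohort_spec()].
#' @return List of [virtual_listener()] objects, length `spec$n_listeners`;
#'   deterministic under the spec's seed.
#' @examples
#' cohort <- sample_cohort(cohort_spec(20, seed = 7))  # 20 listeners, 40 ears
#' length(cohort)
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_listeners), function(i) {
    thr <- data.frame(
      ear = rep(c("right", "left"), each = length(TEST_FREQUENCIES)),
      freq_hz = rep(TEST_FREQUENCIES, 2L),
      threshold_dbhl = pmin(pmax(round(stats::rnorm(
        2L * length(TEST_FREQUENCIES),
        mean = rep(spec$mean_dbhl, 2L),
        sd = rep(spec$sd_dbhl, 2L))), -10), 120))
    virtual_listener(thr, model = spec$model, slope = spec$slope,
                     guess_rate = spec$guess_rate,
                     lapse_rate = spec$lapse_rate,
                     id = sprintf("L%03d", i))
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Miscalibrated-device view of a listener
#'
#' Models testing through a device whose assumed RETSPLs are wrong: if the
#' device's true RETSPL exceeds its assumed value by `delta` dB at some
#' frequency, every tone it plays there is `delta` dB quieter than labelled,
#' so the listener's apparent threshold is `delta` dB higher than the truth.
#' The returned listener responds exactly as the original would to the
#' physically delivered level.
#'
#' @param listener A [virtual_listener()].
#' @param retspl_error Named numeric vector, frequency (Hz) to error in dB
#'   (true RETSPL minus assumed); frequencies not named get error 0.
#' @return A new `virtual_listener` with shifted apparent thresholds.
#' @examples
#' vl <- virtual_listener(rep(10, 6))
#' dev <- as_device_listener(vl, c("250" = 10))
#' run_track(response_fn(dev, "right", 250))$threshold  # 20, not 10
#' @export
as_device_listener <- function(listener, retspl_error) {
  stopifnot(inherits(listener, "virtual_listener"),
            all(is.finite(retspl_error)))
  err <- stats::setNames(rep(0, length(TEST_FREQUENCIES)),
                         as.character(TEST_FREQUENCIES))
  if (length(retspl_error)) {
    if (is.null(names(retspl_error)) &&
        length(retspl_error) == length(TEST_FREQUENCIES))
      names(retspl_error) <- as.character(TEST_FREQUENCIES)
    bad <- setdiff(names(retspl_error), names(err))
    if (length(bad))
      stop("retspl_error names must be test frequencies; unknown: ",
           paste(bad, collapse = ", "), call. = FALSE)
    err[names(retspl_error)] <- as.numeric(retspl_error)
  }
  out <- listener
  out$id <- paste0(listener$id, "+device")
  out$thresholds$threshold_dbhl <- listener$thresholds$threshold_dbhl +
    err[as.character(listener$thresholds$freq_hz)]
  ## apparent thresholds may leave the constructible range; the response model
  ## is still well defined, so bypass the constructor's range check
  out
}

#' Read and write cohort truth tables
#'
#' Cohorts serialize as delimited text with header
#' `listener_id,ear,freq_hz,true_threshold_dbhl`, the ground-truth companion
#' to paired-measurement files consumed by the calibration module.
#'
#' @param cohort List of [virtual_listener()]s.
#' @param path File path.
#' @return `read_cohort_table()`: a data frame in the same column layout.
#' @export
write_cohort_table <- function(cohort, path) {
  rows <- do.call(rbind, lapply(cohort, function(vl) {
    data.frame(listener_id = vl$id, ear = vl$thresholds$ear,
               freq_hz = vl$thresholds$freq_hz,
               true_threshold_dbhl = vl$thresholds$threshold_dbhl)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("listener_id", "ear", "freq_hz", "true_threshold_dbhl")
                %in% names(df)))
  df
}
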