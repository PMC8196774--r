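#' Sentinel for a listener who never responds at the maximum presentable level
#'
#' When a track reaches the device ceiling and the listener still does not
#' respond, no numeric threshold exists; the track terminates with this
#' sentinel instead of fabricating a value.
#'
#' @format A single `NA_real_` carrying class `no_response`.
#' @export
NO_RESPONSE <- structure(NA_real_, class = "no_response")

#' Test whether a threshold is the no-response sentinel
#' @param x A threshold as returned by [run_track()].
#' @return Logical scalar.
#' @export
is_no_response <- function(x) inherits(x, "no_response") || (is.na(as.numeric(x)[1]))

#' @export
print.no_response <- function(x, ...) { cat("NO_RESPONSE (ceiling reached)\n"); invisible(x) }

#' Configuration of one adaptive staircase track
#'
#' Parameters of the modified Hughson-Westlake procedure for a single ear and
#' frequency: the track starts at 30 dB HL, ascends in 10 dB steps until the
#' first response, then alternates 10 dB down after each response with 5 dB up
#' after each miss.  The threshold is the first level heard on an ascending run
#' after the required number of reversals (default three).
#'
#' @param start_level Initial presentation level, dB HL (default 30).
#' @param ascend_step_initial Step during the initial ascent, dB (default 10).
#' @param descend_step Step down after a heard response, dB (default 10).
#' @param ascend_step Step up after a miss in the main phase, dB (default 5).
#' @param reversals_required Reversals before a heard ascending response counts
#'   as threshold (default 3).
#' @param floor Lowest presentable level, dB HL (default -10).
#' @param ceiling Highest presentable level, dB HL; per frequency this is
#'   [max_level_hl()] (default 80).
#' @param max_presentations Hard cap guaranteeing termination with adversarial
#'   or purely random listeners (default 50).
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(start_level = 30, ascend_step_initial = 10,
                             descend_step = 10, ascend_step = 5,
                             reversals_required = 3, floor = -10, ceiling = 80,
                             max_presentations = 50) {
  stopifnot(ascend_step_initial > 0, descend_step > 0, ascend_step > 0,
            reversals_required >= 1, max_presentations >= 1)
  if (!(floor < start_level && start_level <= ceiling))
    stop("need floor < start_level <= ceiling (got floor=", floor,
         ", start=", start_level, ", ceiling=", ceiling, ")", call. = FALSE)
  structure(list(start_level = start_level,
                 ascend_step_initial = ascend_step_initial,
                 descend_step = descend_step, ascend_step = ascend_step,
                 reversals_required = reversals_required,
                 floor = floor, ceiling = ceiling,
                 max_presentations = max_presentations),
            class = "staircase_config")
}

#' Start a staircase track
#'
#' @param config A [staircase_config()].
#' @return A `staircase_state`: fields `current_level` (the level now being
#'   presented), `phase` (`initial_ascent`, `descending`, `ascending`,
#'   `complete` or `no_response`), `reversal_count`, `history` (data frame of
#'   presented level and response) and `threshold` (set only on completion).
#' @export
staircase_start <- function(config = staircase_config()) {
  stopifnot(inherits(config, "staircase_config"))
  structure(list(current_level = config$start_level,
                 phase = "initial_ascent",
                 reversal_count = 0L,
                 history = data.frame(level_dbhl = numeric(0),
                                      heard = logical(0)),
                 threshold = NULL),
            class = "staircase_state")
}

is_terminal <- function(state) state$phase %in% c("complete", "no_response")

#' Advance a staircase track by one presentation
#'
#' Records the listener's response to the current level and applies the
#' staircase rules: during the initial ascent, misses raise the level by 10 dB
#' until the ceiling (a miss at the ceiling terminates with [NO_RESPONSE]) and
#' the first response turns the track down, logging reversal 1.  Thereafter a
#' response lowers the level by 10 dB (clamped at the floor, where a response
#' counts as the turnaround) and a miss raises it by 5 dB, each direction
#' change logging a reversal.  A response on an ascending run with the required
#' reversals already logged completes the track; that level is the threshold.
#'
#' @param state A non-terminal `staircase_state`.
#' @param heard Logical: did the listener respond to `state$current_level`?
#' @param config The [staircase_config()] the track was started with.
#' @return The updated `staircase_state`.
#' @export
staircase_step <- function(state, heard, config = staircase_config()) {
  stopifnot(inherits(state, "staircase_state"), is.logical(heard),
            length(heard) == 1L, !is.na(heard))
  if (is_terminal(state))
    stop("cannot step a terminal staircase (phase: ", state$phase, ")",
         call. = FALSE)
  lvl <- state$current_level
  state$history <- rbind(state$history,
                         data.frame(level_dbhl = lvl, heard = heard))

  clamp <- function(x) min(max(x, config$floor), config$ceiling)

  if (state$phase == "initial_ascent") {
    if (heard) {
      state$reversal_count <- state$reversal_count + 1L  # turn into 1st descent
      state$phase <- "descending"
      state$current_level <- clamp(lvl - config$descend_step)
    } else if (lvl >= config$ceiling) {
      state$phase <- "no_response"
      state$threshold <- NO_RESPONSE
    } else {
      state$current_level <- clamp(lvl + config$ascend_step_initial)
    }
  } else if (state$phase == "descending") {
    if (heard) {
      if (lvl <= config$floor) {
        ## can't go lower: response at the floor is the turnaround point
        state$reversal_count <- state$reversal_count + 1L
        state$phase <- "ascending"
      } else {
        state$current_level <- clamp(lvl - config$descend_step)
      }
    } else {
      state$reversal_count <- state$reversal_count + 1L
      state$phase <- "ascending"
      state$current_level <- clamp(lvl + config$ascend_step)
    }
  } else {  # ascending
    if (heard) {
      if (state$reversal_count >= config$reversals_required) {
        state$phase <- "complete"
        state$threshold <- lvl
      } else {
        state$reversal_count <- state$reversal_count + 1L
        state$phase <- "descending"
        state$current_level <- clamp(lvl - config$descend_step)
      }
    } else if (lvl >= config$ceiling) {
      state$phase <- "no_response"
      state$threshold <- NO_RESPONSE
    } else {
      state$current_level <- clamp(lvl + config$ascend_step)
    }
  }
  state
}

#' @export
print.staircase_state <- function(x, ...) {
  cat("Staircase track: phase", x$phase,
      "| reversals", x$reversal_count,
      "| presentations", nrow(x$history), "\n")
  if (x$phase == "complete")
    cat("  threshold:", format_num(x$threshold), "dB HL\n")
  else if (x$phase == "no_response")
    cat("  threshold: NO_RESPONSE (ceiling)\n")
  else
    cat("  next presentation:", format_num(x$current_level), "dB HL\n")
  invisible(x)
}

#' Run a staircase track to completion against a response function
#'
#' Drives [staircase_step()] with responses drawn from `listener_response`
#' until the track completes or terminates at the ceiling.  A hard cap on the
#' number of presentations guarantees termination even for adversarial
#' responders.
#'
#' @param listener_response Function of one argument (level, dB HL) returning
#'   `TRUE` iff the tone was heard; must be total over `[floor, ceiling]`.
#' @param config A [staircase_config()].
#' @return A list with `threshold` (dB HL, or [NO_RESPONSE]), `history`
#'   (data frame `level_dbhl`, `heard`) and `reversals`.
#' @examples
#' # a deterministic listener with true threshold 40 dB HL
#' run_track(function(level) level >= 40)$threshold
#' @export
run_track <- function(listener_response, config = staircase_config()) {
  stopifnot(is.function(listener_response))
  state <- staircase_start(config)
  while (!is_terminal(state)) {
    if (nrow(state$history) >= config$max_presentations)
      stop("staircase did not converge within ", config$max_presentations,
           " presentations (non-converging listener?)", call. = FALSE)
    heard <- isTRUE(listener_response(state$current_level))
    state <- staircase_step(state, heard, config)
  }
  list(threshold = state$threshold, history = state$history,
       reversals = state$reversal_count)
}

#' Serialize and replay track transcripts
#'
#' A transcript is the presentation history of one track as delimited text with
#' header `presentation_index,level_dbhl,heard`, suitable for audit and exact
#' replay.  `replay_track()` feeds a recorded response sequence back through
#' [staircase_step()] and returns the reconstructed terminal state; replay of a
#' genuine transcript reproduces the recorded levels exactly.
#'
#' @param history Data frame with columns `level_dbhl` and `heard`.
#' @param path File path.
#' @param config The [staircase_config()] used for the original run.
#' @return `replay_track()`: the terminal `staircase_state`.
#' @export
write_transcript <- function(history, path) {
  df <- data.frame(presentation_index = seq_len(nrow(history)),
                   level_dbhl = history$level_dbhl,
                   heard = as.logical(history$heard))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("presentation_index", "level_dbhl", "heard") %in% names(df)))
  df[order(df$presentation_index), c("level_dbhl", "heard")]
}

#' @rdname write_transcript
#' @export
replay_track <- function(history, config = staircase_config()) {
  state <- staircase_start(config)
  for (i in seq_len(nrow(history))) {
    if (is_terminal(state)) break
    if (state$current_level != history$level_dbhl[i])
      stop("transcript does not replay: expected presentation at ",
           state$current_level, " dB HL but transcript has ",
           history$level_dbhl[i], call. = FALSE)
    state <- staircase_step(state, as.logical(history$heard[i]), config)
  }
  state
}
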