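#' @keywords internal
"_PACKAGE"

## The six octave test frequencies, Hz.  Everything in the package is keyed on
## these; lookups at any other frequency are errors by design.
TEST_FREQUENCIES <- c(250L, 500L, 1000L, 2000L, 4000L, 8000L)

#' Supported audiometric test frequencies
#'
#' The six octave frequencies tested by the application: 250, 500, 1000, 2000,
#' 4000 and 8000 Hz.
#'
#' @return Integer vector of frequencies in Hz.
#' @export
test_frequencies <- function() TEST_FREQUENCIES

freq_key <- function(freq) {
  if (length(freq) != 1L || !is.numeric(freq) || !freq %in% TEST_FREQUENCIES)
    stop("unsupported test frequency: ", paste(freq, collapse = ", "),
         " (supported: ", paste(TEST_FREQUENCIES, collapse = ", "), " Hz)",
         call. = FALSE)
  as.character(as.integer(freq))
}

#' Construct a RETSPL table for one transducer profile
#'
#' A RETSPL (reference equivalent threshold sound pressure level) table maps
#' each test frequency to the sound pressure level, in dB SPL, that corresponds
#' to 0 dB HL for a particular transducer.  It is the per-frequency offset in
#' the conversion `dB SPL = dB HL + RETSPL`.
#'
#' @param transducer Character name of the transducer profile.
#' @param values Numeric vector of six RETSPL values (dB SPL), one per test
#'   frequency in ascending order, or a named vector keyed by frequency.
#' @return An object of class `retspl_table`.
#' @examples
#' er3a <- retspl_table("ER-3A", c(14.5, 6, 0, 2.5, 0, -3.5))
#' hl_to_spl(0, 250, er3a)
#' @export
retspl_table <- function(transducer, values) {
  stopifnot(is.character(transducer), length(transducer) == 1L, nzchar(transducer))
  if (!is.null(names(values))) {
    wanted <- as.character(TEST_FREQUENCIES)
    if (!setequal(names(values), wanted))
      stop("named RETSPL values must cover exactly the six test frequencies",
           call. = FALSE)
    values <- values[wanted]
  }
  values <- as.numeric(values)
  if (length(values) != length(TEST_FREQUENCIES))
    stop("need exactly ", length(TEST_FREQUENCIES), " RETSPL values", call. = FALSE)
  if (any(!is.finite(values)))
    stop("RETSPL values must be finite", call. = FALSE)
  if (any(abs(values) > 50))
    stop("implausible RETSPL value (|RETSPL| > 50 dB SPL): ",
         paste(values[abs(values) > 50], collapse = ", "), call. = FALSE)
  names(values) <- as.character(TEST_FREQUENCIES)
  structure(list(transducer = transducer, entries = values),
            class = "retspl_table")
}

#' @export
print.retspl_table <- function(x, ...) {
  cat("RETSPL table:", x$transducer, "\n")
  print(x$entries)
  invisible(x)
}

#' Look up the RETSPL at one frequency
#'
#' @param table A [retspl_table()].
#' @param freq Test frequency in Hz.
#' @return RETSPL in dB SPL.
#' @export
retspl_at <- function(table, freq) {
  stopifnot(inherits(table, "retspl_table"))
  unname(table$entries[[freq_key(freq)]])
}

#' Read and write RETSPL tables
#'
#' RETSPL tables are exchanged as delimited text with header
#' `transducer,f250,f500,f1000,f2000,f4000,f8000`, one row per transducer
#' profile.  [read_retspl_tables()] returns a named list of [retspl_table()]
#' objects; [write_retspl_tables()] serializes a list (or a single table) back
#' to the same format so that a read/write cycle reproduces the values exactly.
#'
#' @param path File path.
#' @param tables A `retspl_table` or list of them.
#' @return `read_retspl_tables()`: a named list of `retspl_table` objects.
#' @export
read_retspl_tables <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wanted <- c("transducer", paste0("f", TEST_FREQUENCIES))
  if (!identical(names(df), wanted))
    stop("RETSPL file must have header ", paste(wanted, collapse = ","),
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    retspl_table(df$transducer[i], as.numeric(df[i, -1])))
  names(out) <- df$transducer
  out
}

#' @rdname read_retspl_tables
#' @export
write_retspl_tables <- function(tables, path) {
  if (inherits(tables, "retspl_table")) tables <- list(tables)
  rows <- vapply(tables, function(tb) {
    paste(c(tb$transducer, vapply(tb$entries, format_num, "")), collapse = ",")
  }, "")
  writeLines(c(paste(c("transducer", paste0("f", TEST_FREQUENCIES)),
                     collapse = ","), rows), path)
  invisible(path)
}

## format numbers without scientific notation or trailing-zero drift
format_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Packaged RETSPL tables
#'
#' The three transducer profiles shipped with the package: `"ER-3A"` (ANSI
#' S3.6-2010 insert-earphone reference values), `"HearTest v1"` (initial
#' estimates borrowed from Apple EarPods measurements) and `"HearTest v2"`
#' (the subjectively calibrated smartphone-earphone values).
#'
#' @param transducer Profile name; omit to get the full named list.
#' @return A `retspl_table`, or a named list of all three.
#' @examples
#' retspl_at(packaged_retspl("ER-3A"), 250)
#' @export
packaged_retspl <- function(transducer = NULL) {
  tables <- read_retspl_tables(
    system.file("extdata", "retspl_tables.csv", package = "puretone",
                mustWork = TRUE))
  if (is.null(transducer)) return(tables)
  if (!transducer %in% names(tables))
    stop("no packaged RETSPL profile named '", transducer, "' (have: ",
         paste(names(tables), collapse = ", "), ")", call. = FALSE)
  tables[[transducer]]
}

## ---- level unit discipline -------------------------------------------------

#' Hearing-level and sound-pressure-level values
#'
#' Thin unit wrappers keeping dB HL and dB SPL distinct.  `level_hl()` enforces
#' the audiometric constructible range \[-10, 120\] dB HL; `level_spl()`
#' requires a finite value.  Both are plain numerics with a class attribute and
#' behave as numbers in arithmetic.
#'
#' @param value Numeric level in dB.
#' @return A classed numeric of class `level_hl` or `level_spl`.
#' @export
level_hl <- function(value) {
  value <- as.numeric(value)
  stopifnot(length(value) == 1L)
  if (!is.finite(value) || value < -10 || value > 120)
    stop("dB HL value must lie in [-10, 120], got ", value, call. = FALSE)
  structure(value, class = "level_hl")
}

#' @rdname level_hl
#' @export
level_spl <- function(value) {
  value <- as.numeric(value)
  stopifnot(length(value) == 1L)
  if (!is.finite(value))
    stop("dB SPL value must be finite", call. = FALSE)
  structure(value, class = "level_spl")
}

#' @export
print.level_hl <- function(x, ...) { cat(format_num(unclass(x)), "dB HL\n"); invisible(x) }
#' @export
print.level_spl <- function(x, ...) { cat(format_num(unclass(x)), "dB SPL\n"); invisible(x) }

#' Convert between dB HL and dB SPL through a RETSPL table
#'
#' The defining relation of audiometric calibration is
#' `dB SPL = dB HL + RETSPL(f)`: hearing level is sound pressure level
#' re-referenced to the normal-hearing threshold of the transducer at each
#' frequency.  `hl_to_spl()` applies the relation; `spl_to_hl()` inverts it, so
#' the two round-trip exactly at every supported frequency.
#'
#' @param level Level in dB HL (for `hl_to_spl`) or dB SPL (for `spl_to_hl`);
#'   a bare numeric or a [level_hl()]/[level_spl()] object.
#' @param freq Test frequency in Hz (one of the six supported).
#' @param table A [retspl_table()] containing `freq`.
#' @return A [level_spl()] (resp. [level_hl()]) object.
#' @examples
#' hl_to_spl(0, 250, packaged_retspl("ER-3A"))    # 14.5 dB SPL
#' spl_to_hl(14.5, 250, packaged_retspl("ER-3A")) # 0 dB HL
#' @export
hl_to_spl <- function(level, freq, table) {
  level_spl(as.numeric(level) + retspl_at(table, freq))
}

#' @rdname hl_to_spl
#' @export
spl_to_hl <- function(level, freq, table) {
  x <- as.numeric(level) - retspl_at(table, freq)
  ## constructible-range check belongs to level_hl(); conversion itself is exact
  level_hl(x)
}

## ---- severity classification ----------------------------------------------

## ASHA hearing-loss bands.  The printed severe band is 71-90 and profound is
## ">= 90"; 90 is assigned to severe so the bands partition the axis (profound
## starts strictly above 90).  Thresholds below 0 dB HL are normal.
ASHA_CATEGORIES <- data.frame(
  label = c("normal", "mild", "moderate", "moderately_severe", "severe",
            "profound"),
  lower = c(-Inf, 25, 40, 55, 70, 90),
  upper = c(25, 40, 55, 70, 90, Inf),   # interval (lower, upper]
  stringsAsFactors = FALSE
)

#' ASHA severity categories
#'
#' The six-level American Speech-Language-Hearing Association stratification of
#' hearing loss: normal (0--25 dB HL), mild (26--40), moderate (41--55),
#' moderately severe (56--70), severe (71--90) and profound (above 90).
#' Returned bounds describe half-open intervals `(lower, upper]`; thresholds
#' below 0 dB HL count as normal.
#'
#' @return A data frame with columns `label`, `lower`, `upper`.
#' @export
hearing_categories <- function() ASHA_CATEGORIES

#' Classify a hearing threshold into an ASHA severity category
#'
#' @param threshold Threshold in dB HL (numeric or [level_hl()]); may be a
#'   vector.
#' @return Character vector of category labels, one of `"normal"`, `"mild"`,
#'   `"moderate"`, `"moderately_severe"`, `"severe"`, `"profound"`.
#' @examples
#' classify_threshold(25)   # "normal"
#' classify_threshold(41)   # "moderate"
#' @export
classify_threshold <- function(threshold) {
  x <- as.numeric(threshold)
  if (any(!is.finite(x)))
    stop("threshold must be finite; NO_RESPONSE cells have no category",
         call. = FALSE)
  ## band i is (lower_i, upper_i]: count uppers strictly below x
  idx <- findInterval(x, ASHA_CATEGORIES$upper, left.open = TRUE) + 1L
  ASHA_CATEGORIES$label[idx]
}

#' Maximum presentable level per frequency
#'
#' The smartphone output ceiling limits the testable range to -10..80 dB HL,
#' except at 250 Hz where the ceiling is 75 dB HL.
#'
#' @param freq Test frequency in Hz.
#' @return Ceiling in dB HL.
#' @examples
#' max_level_hl(250)   # 75
#' max_level_hl(1000)  # 80
#' @export
max_level_hl <- function(freq) {
  freq_key(freq)  # validates
  if (as.integer(freq) == 250L) 75 else 80
}
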