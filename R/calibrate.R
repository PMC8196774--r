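#' Paired audiometer/device threshold measurements
#'
#' One row per ear and frequency: the threshold measured by the reference
#' clinical audiometer and the threshold measured by the smartphone device for
#' the same ear.  Rows where either instrument recorded no response at its
#' ceiling carry `NA`; they are excluded from all statistics with a logged
#' count, since no numeric threshold exists.
#'
#' @param data Data frame with columns `ear_id`, `freq_hz`,
#'   `audiometer_dbhl`, `device_dbhl` (`NA` marks a no-response cell).
#' @return An object of class `paired_measurements`; attribute `n_excluded`
#'   counts dropped no-response rows.
#' @export
paired_measurements <- function(data) {
  need <- c("ear_id", "freq_hz", "audiometer_dbhl", "device_dbhl")
  stopifnot(is.data.frame(data), all(need %in% names(data)))
  data <- data[, need]
  if (anyDuplicated(data[, c("ear_id", "freq_hz")]))
    stop("duplicate (ear_id, freq_hz) rows", call. = FALSE)
  if (!all(data$freq_hz %in% TEST_FREQUENCIES))
    stop("freq_hz must be one of the six test frequencies", call. = FALSE)
  drop <- !is.finite(data$audiometer_dbhl) | !is.finite(data$device_dbhl)
  n_excluded <- sum(drop)
  if (n_excluded)
    warning(n_excluded, " no-response row(s) excluded from calibration",
            call. = FALSE)
  data <- data[!drop, , drop = FALSE]
  vals <- c(data$audiometer_dbhl, data$device_dbhl)
  if (length(vals) && (min(vals) < -10 || max(vals) > 120))
    stop("thresholds must lie in [-10, 120] dB HL", call. = FALSE)
  structure(data, class = c("paired_measurements", "data.frame"),
            n_excluded = n_excluded)
}

#' Read and write paired-measurement files
#'
#' Delimited text with header `ear_id,freq_hz,audiometer_dbhl,device_dbhl`;
#' the literal token `NR` (or an empty field) marks a no-response cell.
#'
#' @param path File path.
#' @param data A [paired_measurements()] object or compatible data frame.
#' @return `read_paired_measurements()`: a `paired_measurements` object.
#' @export
read_paired_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "NR", ""))
  df$audiometer_dbhl <- as.numeric(df$audiometer_dbhl)
  df$device_dbhl <- as.numeric(df$device_dbhl)
  paired_measurements(df)
}

#' @rdname read_paired_measurements
#' @export
write_paired_measurements <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE,
                   na = "NR")
  invisible(path)
}

#' Per-frequency median threshold difference
#'
#' For each frequency, the median over ears of (audiometer threshold minus
#' device threshold).  The median, rather than the mean, is used because
#' measured thresholds are not normally distributed and the median resists
#' outliers; with an even number of ears it is the midpoint of the two central
#' values, which is how non-5-dB-grid corrections arise.
#'
#' @param data A [paired_measurements()] object.
#' @param frequencies Frequencies the result must cover (default: those
#'   present in `data`); any requested frequency with zero valid pairs is an
#'   error naming that frequency.
#' @return Named numeric vector, frequency (Hz) to median difference in dB.
#' @examples
#' pm <- paired_measurements(data.frame(
#'   ear_id = 1:3, freq_hz = 1000,
#'   audiometer_dbhl = c(10, 15, 20), device_dbhl = 20))
#' median_threshold_difference(pm)  # 1000 Hz: -5
#' @export
median_threshold_difference <- function(data, frequencies = NULL) {
  stopifnot(inherits(data, "paired_measurements"))
  if (is.null(frequencies)) frequencies <- sort(unique(data$freq_hz))
  missing <- setdiff(as.character(frequencies),
                     as.character(unique(data$freq_hz)))
  if (length(missing))
    stop("no valid pairs at frequency ", paste(missing, collapse = ", "),
         " Hz", call. = FALSE)
  vapply(split(data, factor(data$freq_hz, levels = frequencies)),
         function(sub) stats::median(sub$audiometer_dbhl - sub$device_dbhl),
         0)
}

#' Correct a RETSPL table from median threshold differences
#'
#' A device whose assumed RETSPL differs from its true value measures every
#' threshold offset by that difference.  Writing `m(f)` for the median of
#' (audiometer minus device) thresholds, the relation
#' `SPL = HL + RETSPL` gives `RETSPL_true = RETSPL_assumed - m(f)`, so the
#' corrected table is the old table minus the per-frequency median difference.
#'
#' @param old The assumed [retspl_table()].
#' @param med_diff Named vector from [median_threshold_difference()]; must
#'   cover all six frequencies.
#' @param transducer Name for the corrected profile (default appends
#'   `" (corrected)"`).
#' @return A new [retspl_table()].
#' @examples
#' v1 <- packaged_retspl("HearTest v1")
#' med <- setNames(c(10, 15, 5, -5, -7, 2.5), test_frequencies())
#' correct_retspl(v1, med)
#' @export
correct_retspl <- function(old, med_diff,
                           transducer = paste(old$transducer, "(corrected)")) {
  stopifnot(inherits(old, "retspl_table"))
  wanted <- as.character(TEST_FREQUENCIES)
  if (!all(wanted %in% names(med_diff)))
    stop("median differences missing frequency ",
         paste(setdiff(wanted, names(med_diff)), collapse = ", "),
         call. = FALSE)
  retspl_table(transducer, old$entries - as.numeric(med_diff[wanted]))
}

#' Spearman rank correlation between audiometer and device thresholds
#'
#' Rank correlation is used because threshold data are ordinal-ish, not
#' normally distributed, and may contain outliers.  Ranks use the average-rank
#' convention for ties; rho is the Pearson correlation of the rank vectors.
#' The two-sided p-value uses exact permutation enumeration for fewer than 10
#' pairs and the large-sample t approximation otherwise.
#'
#' @param data A [paired_measurements()] object (pairs pooled across
#'   frequencies), or any data frame with `audiometer_dbhl`/`device_dbhl`.
#' @return List with elements `rho`, `p_value` and `n`.
#' @export
spearman_rank_correlation <- function(data) {
  x <- data$audiometer_dbhl; y <- data$device_dbhl
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  rho <- spearman_rho(x, y)
  p <- if (n < 10) spearman_p_exact(x, y, rho) else spearman_p_t(rho, n)
  list(rho = rho, p_value = p, n = n)
}

spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

spearman_p_t <- function(rho, n) {
  if (is.na(rho) || abs(rho) >= 1) return(if (is.na(rho)) NA_real_ else 0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

## exact two-sided permutation p-value: enumerate all n! rank assignments
spearman_p_exact <- function(x, y, rho_obs) {
  n <- length(x)
  perms <- permutations(n)
  rhos <- apply(perms, 1L, function(idx) spearman_rho(x, y[idx]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Per-frequency mean absolute error between instruments
#'
#' @param data A [paired_measurements()] object.
#' @return Data frame with columns `freq_hz`, `mae_dbhl` (mean of
#'   |audiometer - device|), `sd_dbhl` (SD of the absolute errors) and `n`.
#' @export
mean_absolute_error <- function(data) {
  stopifnot(inherits(data, "paired_measurements"))
  out <- do.call(rbind, lapply(split(data, data$freq_hz), function(sub) {
    e <- abs(sub$audiometer_dbhl - sub$device_dbhl)
    data.frame(freq_hz = sub$freq_hz[1], mae_dbhl = mean(e),
               sd_dbhl = if (length(e) > 1) stats::sd(e) else 0,
               n = length(e))
  }))
  rownames(out) <- NULL
  out[order(out$freq_hz), ]
}

#' Simulate a paired audiometer/device threshold experiment
#'
#' The desk analogue of a calibration study: each cohort member is tested
#' twice per ear and frequency — once as-is (the reference audiometer, whose
#' RETSPLs are correct by construction) and once through
#' [as_device_listener()] with the injected per-frequency RETSPL errors (the
#' miscalibrated smartphone).  Cells where either run hits the ceiling become
#' no-response rows.
#'
#' @param cohort List of [virtual_listener()]s (see [sample_cohort()]).
#' @param retspl_error Named per-frequency error in dB (true minus assumed
#'   RETSPL); see [as_device_listener()].
#' @param staircase Baseline [staircase_config()]; ceilings come from
#'   [max_level_hl()] per frequency.
#' @param seed Optional seed for stochastic response models.
#' @return A [paired_measurements()] object covering every ear of the cohort.
#' @examples
#' cohort <- sample_cohort(cohort_spec(5, seed = 3))
#' pm <- simulate_paired_measurements(cohort, c("250" = 10))
#' median_threshold_difference(pm)["250"]   # close to -10
#' @export
simulate_paired_measurements <- function(cohort, retspl_error = numeric(0),
                                         staircase = staircase_config(),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", 0L)
  for (vl in cohort) {
    dev <- as_device_listener(vl, retspl_error)
    for (ear in c("right", "left")) {
      for (f in TEST_FREQUENCIES) {
        cfg <- staircase
        cfg$ceiling <- max_level_hl(f)
        aud <- run_track(response_fn(vl, ear, f), cfg)$threshold
        dvc <- run_track(response_fn(dev, ear, f), cfg)$threshold
        rows[[length(rows) + 1L]] <- data.frame(
          ear_id = paste(vl$id, ear, sep = "_"), freq_hz = f,
          audiometer_dbhl = if (is_no_response(aud)) NA_real_
                            else as.numeric(aud),
          device_dbhl = if (is_no_response(dvc)) NA_real_
                        else as.numeric(dvc))
      }
    }
  }
  paired_measurements(do.call(rbind, rows))
}

## ---- device max-output analysis -------------------------------------------

#' Read a device maximum-output table
#'
#' Delimited text with header `device,channel,f250,...,f8000`: the maximum
#' output in dB SPL each device/channel can produce at each test frequency, as
#' measured with a 2-cc coupler.
#'
#' @param path File path; defaults to the packaged iPhone XR/10/8 +
#'   Sennheiser CX300 measurements.
#' @return Long data frame with columns `device`, `channel`, `freq_hz`,
#'   `max_output_spl`, class `device_output_table`.
#' @export
read_device_output_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "device_max_output.csv",
                        package = "puretone", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wanted <- c("device", "channel", paste0("f", TEST_FREQUENCIES))
  if (!identical(names(df), wanted))
    stop("device output file must have header ",
         paste(wanted, collapse = ","), call. = FALSE)
  long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    data.frame(device = df$device[i], channel = df$channel[i],
               freq_hz = TEST_FREQUENCIES,
               max_output_spl = as.numeric(df[i, -(1:2)]))))
  if (any(!is.finite(long$max_output_spl)))
    stop("max outputs must be finite", call. = FALSE)
  structure(long, class = c("device_output_table", "data.frame"))
}

#' Inter-device spread of maximum output levels
#'
#' For each (frequency, channel) cell, the range (max minus min) of the
#' maximum output across devices; the overall maximum of these spreads
#' quantifies how interchangeable the devices are.  For the packaged iPhone
#' measurements the overall maximum spread is 2.0 dB SPL (250 Hz, left
#' channel), low enough to support sharing one calibration across devices of
#' the same brand.
#'
#' @param table A `device_output_table` (default the packaged one).
#' @return List with `per_cell` (data frame `freq_hz`, `channel`,
#'   `spread_db`) and `overall_max_db`.
#' @examples
#' device_output_spread()$overall_max_db  # 2.0
#' @export
device_output_spread <- function(table = read_device_output_table()) {
  stopifnot(inherits(table, "data.frame"))
  if (length(unique(table$device)) < 2)
    stop("need at least 2 devices to compute a spread", call. = FALSE)
  per <- do.call(rbind, lapply(
    split(table, list(table$freq_hz, table$channel)), function(sub)
      data.frame(freq_hz = sub$freq_hz[1], channel = sub$channel[1],
                 spread_db = max(sub$max_output_spl) -
                   min(sub$max_output_spl))))
  rownames(per) <- NULL
  per <- per[order(per$freq_hz, per$channel), ]
  list(per_cell = per, overall_max_db = max(per$spread_db))
}

## ---- the calibration fit ---------------------------------------------------

#' Calibrate a device RETSPL table from paired threshold measurements
#'
#' The central estimator of the package: given paired audiometer/device
#' thresholds for a cohort of ears and the RETSPL table the device assumed
#' during testing, estimate the per-frequency calibration error as the median
#' threshold difference and return the corrected table together with the
#' agreement statistics (Spearman rank correlation, per-frequency mean
#' absolute error) that describe the pre-calibration fit.
#'
#' @param data A [paired_measurements()] object (or data frame coercible to
#'   one).
#' @param table The assumed [retspl_table()] under which `device_dbhl` was
#'   measured.
#' @param transducer Name for the corrected profile.
#' @return An object of class `retspl_calibration` with components
#'   `med_diff`, `corrected` (the new [retspl_table()]), `spearman`, `mae`,
#'   `n_ears`, `n_excluded` and `data`.  Methods: [coef()] (the per-frequency
#'   median differences), [predict()] (apply the correction to device-measured
#'   thresholds), [residuals()] (audiometer minus corrected device
#'   thresholds), `print()` and `summary()`.
#' @examples
#' pm <- paired_measurements(data.frame(
#'   ear_id = rep(1:4, each = 6), freq_hz = rep(test_frequencies(), 4),
#'   audiometer_dbhl = rep(c(10, 15, 10, 5), each = 6),
#'   device_dbhl = rep(c(20, 25, 20, 15), each = 6)))
#' fit <- calibrate_retspl(pm, packaged_retspl("HearTest v1"))
#' coef(fit)   # -10 at every frequency
#' @export
calibrate_retspl <- function(data, table,
                             transducer = paste(table$transducer,
                                                "(corrected)")) {
  if (!inherits(data, "paired_measurements"))
    data <- paired_measurements(data)
  stopifnot(inherits(table, "retspl_table"))
  med <- median_threshold_difference(data, frequencies = TEST_FREQUENCIES)
  corrected <- correct_retspl(table, med, transducer = transducer)
  structure(list(med_diff = med, corrected = corrected, assumed = table,
                 spearman = spearman_rank_correlation(data),
                 mae = mean_absolute_error(data),
                 n_ears = length(unique(data$ear_id)),
                 n_excluded = attr(data, "n_excluded"),
                 data = data, call = match.call()),
            class = "retspl_calibration")
}

#' @export
coef.retspl_calibration <- function(object, ...) object$med_diff

#' Apply a calibration to device-measured thresholds
#'
#' A device retested with the corrected table would measure thresholds shifted
#' by the per-frequency median difference, so the calibrated estimate of a
#' threshold measured under the old table is `device_dbhl + med_diff(f)`.
#'
#' @param object A `retspl_calibration` fit.
#' @param newdata Data frame with columns `freq_hz` and `device_dbhl`;
#'   defaults to the fitting data.
#' @param ... Unused.
#' @return Numeric vector of calibrated thresholds, dB HL.
#' @export
predict.retspl_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  stopifnot(all(c("freq_hz", "device_dbhl") %in% names(newdata)))
  newdata$device_dbhl + object$med_diff[as.character(newdata$freq_hz)]
}

#' @export
residuals.retspl_calibration <- function(object, ...) {
  object$data$audiometer_dbhl - predict(object)
}

#' @export
print.retspl_calibration <- function(x, ...) {
  cat("RETSPL calibration from", nrow(x$data), "paired thresholds (",
      x$n_ears, "ears )\n")
  cat("Per-frequency median difference (audiometer - device), dB:\n")
  print(x$med_diff)
  cat("Corrected table:\n")
  print(x$corrected)
  invisible(x)
}

#' @export
summary.retspl_calibration <- function(object, ...) {
  post <- abs(residuals(object))
  post_mae <- vapply(split(post, object$data$freq_hz), mean, 0)
  out <- list(med_diff = object$med_diff,
              spearman = object$spearman,
              mae_before = object$mae,
              mae_after = post_mae,
              n_excluded = object$n_excluded)
  class(out) <- "summary.retspl_calibration"
  out
}

#' @export
print.summary.retspl_calibration <- function(x, ...) {
  cat("Calibration report\n")
  cat(sprintf("Spearman rho (pre-calibration) = %.3f, p = %.3g, n = %d\n",
              x$spearman$rho, x$spearman$p_value, x$spearman$n))
  cat("Per-frequency median difference (dB):\n"); print(x$med_diff)
  cat("MAE before correction (dB HL):\n")
  print(x$mae_before, row.names = FALSE)
  cat("MAE after applying the correction in-sample (dB HL):\n")
  print(round(x$mae_after, 3))
  if (x$n_excluded)
    cat(x$n_excluded, "no-response row(s) were excluded\n")
  invisible(x)
}
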