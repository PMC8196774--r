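test_that("median differences: single pair, brute-force median, identity", {
  one <- paired_measurements(data.frame(ear_id = 1, freq_hz = 1000,
                                        audiometer_dbhl = 10,
                                        device_dbhl = 20))
  expect_equal(unname(median_threshold_difference(one)), -10)
  three <- paired_measurements(data.frame(ear_id = 1:3, freq_hz = 500,
                                          audiometer_dbhl = c(10, 15, 20),
                                          device_dbhl = 20))
  expect_equal(unname(median_threshold_difference(three)),
               median(c(-10, -5, 0)))
  same <- flat_paired(offset = 0)
  expect_true(all(median_threshold_difference(same) == 0))
})

test_that("even-count medians are midpoints of the central values", {
  pm <- paired_measurements(data.frame(
    ear_id = 1:4, freq_hz = 2000,
    audiometer_dbhl = c(10, 15, 20, 40), device_dbhl = c(20, 20, 20, 21)))
  # diffs -10, -5, 0, 19 -> midpoint of (-5, 0)
  expect_equal(unname(median_threshold_difference(pm)), -2.5)
})

test_that("median differences are permutation- and shift-invariant", {
  pm <- simulate_paired_measurements(
    sample_cohort(cohort_spec(6, sd_dbhl = 7, seed = 12)),
    c("500" = 8, "4000" = -6))
  base <- median_threshold_difference(pm)
  shuffled <- paired_measurements(
    as.data.frame(pm)[sample.int(nrow(pm)), ])
  expect_equal(median_threshold_difference(shuffled), base)
  shifted <- as.data.frame(pm)
  shifted$audiometer_dbhl <- shifted$audiometer_dbhl + 7
  shifted$device_dbhl <- shifted$device_dbhl + 7
  expect_equal(median_threshold_difference(paired_measurements(shifted)),
               base)
})

test_that("frequencies with no valid pairs raise an error naming them", {
  pm <- paired_measurements(data.frame(ear_id = 1, freq_hz = 1000,
                                       audiometer_dbhl = 10,
                                       device_dbhl = 10))
  expect_error(median_threshold_difference(pm, frequencies = c(1000, 250)),
               "250")
})

test_that("no-response rows are excluded with a warning count", {
  df <- data.frame(ear_id = rep(1:2, each = 6),
                   freq_hz = rep(test_frequencies(), 2),
                   audiometer_dbhl = 10, device_dbhl = 12)
  df$device_dbhl[3] <- NA
  expect_warning(pm <- paired_measurements(df), "1 no-response")
  expect_equal(attr(pm, "n_excluded"), 1L)
  expect_equal(nrow(pm), 11)
})

test_that("correct_retspl subtracts the median difference (v1 -> v2 rows)", {
  v1 <- packaged_retspl("HearTest v1")
  med <- stats::setNames(rep(0, 6), as.character(test_frequencies()))
  # v1 overstated the 250 Hz RETSPL by 10, so its tones were 10 dB louder
  # than labelled and it under-read thresholds: median(aud - dev) = +10
  med["250"] <- 10
  corrected <- correct_retspl(v1, med)
  expect_equal(unname(corrected$entries["250"]), 1.8)  # 11.8 - 10
  expect_equal(unname(corrected$entries["500"]), 9.5)
  expect_identical(correct_retspl(v1, med * 0)$entries, v1$entries)
  expect_error(correct_retspl(v1, med[-1]), "missing")
})

test_that("Spearman rho handles monotone, reversed and hand-computed cases", {
  mono <- data.frame(audiometer_dbhl = 1:8, device_dbhl = (1:8) * 2)
  expect_equal(spearman_rank_correlation(mono)$rho, 1)
  rev <- data.frame(audiometer_dbhl = 1:8, device_dbhl = 8:1)
  expect_equal(spearman_rank_correlation(rev)$rho, -1)
  tri <- data.frame(audiometer_dbhl = c(1, 2, 3), device_dbhl = c(2, 1, 3))
  expect_equal(spearman_rank_correlation(tri)$rho, 0.5)
  expect_error(spearman_rank_correlation(tri[1:2, ]), "at least 3")
})

test_that("Spearman rho and large-sample p agree with the reference routine", {
  set.seed(88)
  x <- rnorm(40); y <- x + rnorm(40)
  ours <- spearman_rank_correlation(
    data.frame(audiometer_dbhl = x, device_dbhl = y))
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  # large-sample t approximation tracks the reference p to a few percent
  expect_equal(ours$p_value, ref$p.value, tolerance = 0.2)
  # average-rank tie handling
  xt <- c(1, 1, 2, 3, 4, 4, 5, 6, 7, 8, 9, 10)
  yt <- c(2, 1, 1, 3, 5, 4, 4, 6, 8, 7, 9, 10)
  ours_t <- spearman_rank_correlation(
    data.frame(audiometer_dbhl = xt, device_dbhl = yt))
  expect_equal(ours_t$rho, cor(xt, yt, method = "spearman"),
               tolerance = 1e-12)
})

test_that("mean absolute error: identity, constant offset, arithmetic case", {
  expect_true(all(mean_absolute_error(flat_paired(0))$mae_dbhl == 0))
  off <- mean_absolute_error(flat_paired(5))
  expect_true(all(off$mae_dbhl == 5))
  expect_true(all(off$sd_dbhl == 0))
  two <- paired_measurements(data.frame(
    ear_id = 1:2, freq_hz = 1000,
    audiometer_dbhl = c(10, 10), device_dbhl = c(10, 20)))
  expect_equal(mean_absolute_error(two)$mae_dbhl, 5)  # {0, 10}
})

test_that("device output spread matches the published 2 dB maximum", {
  res <- device_output_spread()
  expect_equal(res$overall_max_db, 2.0)
  worst <- res$per_cell[which.max(res$per_cell$spread_db), ]
  expect_equal(worst$freq_hz, 250)
  expect_equal(worst$channel, "L")
  # identity and synthetic-difference cases
  tab <- read_device_output_table()
  same <- tab[tab$device == "iPhone XR", ]
  same2 <- same; same2$device <- "clone"
  expect_equal(device_output_spread(rbind(same, same2))$overall_max_db, 0)
  bump <- same2; bump$max_output_spl[1] <- bump$max_output_spl[1] + 3
  expect_equal(device_output_spread(rbind(same, bump))$overall_max_db, 3)
  expect_error(device_output_spread(same), "at least 2 devices")
})

test_that("calibration recovers injected RETSPL errors within 2.5 dB and MAE never worsens", {
  delta <- stats::setNames(c(-15, -10, -4, 0, 7, 15),
                           as.character(test_frequencies()))
  cohort <- sample_cohort(cohort_spec(20, mean_dbhl = 10, sd_dbhl = 8,
                                      seed = 42))      # 40 ears
  pm <- simulate_paired_measurements(cohort, delta)
  v1 <- packaged_retspl("HearTest v1")
  truth <- retspl_table("truth", v1$entries + delta)
  fit <- calibrate_retspl(pm, v1)
  expect_true(all(abs(fit$corrected$entries - truth$entries) <= 2.5))
  # post-calibration MAE (device rescored with the corrected table)
  pre <- mean_absolute_error(pm)$mae_dbhl
  post <- vapply(split(abs(residuals(fit)), fit$data$freq_hz), mean, 0)
  expect_true(all(post <= pre + 1e-9))
})

test_that("calibration improves Spearman agreement when errors are large", {
  # opposing errors >= 10 dB scramble the pooled ranking pre-calibration
  delta <- stats::setNames(c(15, -15, 12, -12, 10, -10),
                           as.character(test_frequencies()))
  cohort <- sample_cohort(cohort_spec(20, mean_dbhl = 10, sd_dbhl = 6,
                                      seed = 17))
  pm <- simulate_paired_measurements(cohort, delta)
  fit <- calibrate_retspl(pm, packaged_retspl("HearTest v1"))
  pre_rho <- fit$spearman$rho
  post <- data.frame(audiometer_dbhl = fit$data$audiometer_dbhl,
                     device_dbhl = predict(fit))
  post_rho <- spearman_rank_correlation(post)$rho
  expect_gt(post_rho, pre_rho)
})

test_that("the calibration fit object behaves like a model fit", {
  pm <- flat_paired(offset = -10)   # device reads 10 dB high everywhere
  fit <- calibrate_retspl(pm, packaged_retspl("HearTest v1"))
  expect_s3_class(fit, "retspl_calibration")
  expect_equal(unname(coef(fit)), rep(-10, 6))
  expect_equal(unname(predict(fit)), pm$audiometer_dbhl)
  expect_true(all(residuals(fit) == 0))
  expect_output(print(fit), "median difference")
  expect_output(print(summary(fit)), "Spearman rho")
  # identity: zero offset leaves the table unchanged
  fit0 <- calibrate_retspl(flat_paired(0), packaged_retspl("HearTest v1"))
  expect_identical(fit0$corrected$entries,
                   packaged_retspl("HearTest v1")$entries)
})

test_that("paired measurements round-trip through the delimited format", {
  df <- data.frame(ear_id = rep(1:2, each = 6),
                   freq_hz = rep(test_frequencies(), 2),
                   audiometer_dbhl = 10, device_dbhl = 12)
  df$device_dbhl[5] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_paired_measurements(df, path)   # raw rows keep the NR marker
  expect_true(any(grepl("NR", readLines(path))))
  suppressWarnings(back <- read_paired_measurements(path))
  expect_equal(nrow(back), 11)
})
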