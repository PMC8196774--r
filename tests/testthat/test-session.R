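test_that("a deterministic normal-hearing listener yields twelve 10 dB HL cells", {
  ag <- run_session(virtual_listener(rep(10, 6)))
  df <- as.data.frame(ag)
  expect_equal(nrow(df), 12)
  expect_true(all(df$threshold_dbhl == 10))
  expect_true(all(df$category == "normal"))
  expect_false(any(df$no_response))
  # right ear first, frequencies ascending
  expect_equal(df$ear[1:6], rep("right", 6))
  expect_equal(df$freq_hz[1:6], test_frequencies())
})

test_that("a threshold above the 250 Hz ceiling terminates NO_RESPONSE there", {
  thr <- c("250" = 100, "500" = 20, "1000" = 20, "2000" = 20, "4000" = 20,
           "8000" = 20)
  ag <- run_session(virtual_listener(thr[as.character(test_frequencies())]))
  df <- as.data.frame(ag)
  at250 <- df[df$freq_hz == 250, ]
  expect_true(all(at250$no_response))
  expect_true(all(is.na(at250$threshold_dbhl)))
  expect_false(any(df$no_response[df$freq_hz != 250]))
  # ceiling respected in the transcript
  h <- ag$transcripts[["right_250"]]
  expect_equal(max(h$level_dbhl), 75)
})

test_that("sessions over deterministic listeners are pure functions of inputs", {
  vl <- virtual_listener(c(5, 10, 15, 20, 25, 30))
  a <- run_session(vl); b <- run_session(vl)
  a$created <- b$created <- NULL
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_audiogram(run_session(vl), p1)
  write_audiogram(run_session(vl), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("session transcripts replay to the identical audiogram", {
  set.seed(5)
  vl <- virtual_listener(rep(15, 6), model = "logistic")
  ag <- run_session(vl, seed = 99)
  transcript <- do.call(rbind, lapply(names(ag$transcripts), function(key) {
    parts <- strsplit(key, "_")[[1]]
    cbind(data.frame(ear = parts[1], freq_hz = as.integer(parts[2])),
          ag$transcripts[[key]])
  }))
  replayed <- run_session(transcript)
  expect_equal(as.data.frame(replayed)[, c("ear", "freq_hz", "threshold_dbhl",
                                           "no_response", "category")],
               as.data.frame(ag)[, c("ear", "freq_hz", "threshold_dbhl",
                                     "no_response", "category")])
})

test_that("the ambient pause rule is strict and pauses annotate metadata", {
  expect_true(should_pause(45))
  expect_false(should_pause(40))
  expect_false(should_pause(35))
  expect_true(should_pause(50.01, session_config(noise_pause_threshold = 50)))
  noisy <- local({ i <- 0; function() { i <<- i + 1; if (i == 3) 55 else 30 } })
  ag <- run_session(virtual_listener(rep(10, 6)), ambient_monitor = noisy)
  expect_equal(length(ag$pauses), 1)
  expect_equal(ag$pauses[[1]]$ambient_spl, 55)
  # responses were not discarded: audiogram identical to the quiet run
  quiet <- run_session(virtual_listener(rep(10, 6)))
  expect_equal(as.data.frame(ag), as.data.frame(quiet))
})

test_that("masking level is presentation minus IA, floored at none-needed", {
  expect_equal(as.numeric(masking_level(60, masking_params(40))), 20)
  expect_null(masking_level(40, masking_params(40)))
  expect_null(masking_level(30, masking_params(40)))
  expect_equal(as.numeric(masking_level(100, masking_params(40))), 60)
  # monotone increasing in presentation, decreasing in IA
  lv <- function(p, ia) {
    m <- masking_level(p, masking_params(ia))
    if (is.null(m)) 0 else as.numeric(m)
  }
  pres <- seq(35, 110, by = 5)
  expect_true(all(diff(vapply(pres, lv, 0, ia = 40)) >= 0))
  ias <- seq(20, 70, by = 10)
  expect_true(all(diff(vapply(ias, function(ia) lv(90, ia), 0)) <= 0))
})

test_that("audiograms serialize to JSON and flat table and read back", {
  vl <- virtual_listener(c(10, 15, 20, 30, 45, 100))
  ag <- run_session(vl)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_audiogram(ag, jp)
  write_audiogram_table(ag, cp)
  back <- read_audiogram(jp)
  left <- as.data.frame(back)
  orig <- as.data.frame(ag)
  key <- function(d) d[order(d$ear, d$freq_hz),
                       c("ear", "freq_hz", "threshold_dbhl", "no_response",
                         "category")]
  expect_equal(key(left), key(orig), ignore_attr = TRUE)
  flat <- read.csv(cp)
  expect_equal(nrow(flat), 12)
  expect_true(all(flat$no_response[flat$freq_hz == 8000]))
})

test_that("audiogram plotting runs in clinical orientation without error", {
  ag <- run_session(virtual_listener(c(10, 15, 20, 30, 45, 100)))
  tf <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(tf)
  expect_no_error(plot(ag))
  grDevices::dev.off()
  expect_true(file.size(tf) > 0)
})

test_that("stochastic audiograms stay within ±5 dB of truth in ≥95% of cells", {
  # logistic listeners at the simulator defaults (scale 0.5 dB,
  # guess = lapse = 0.01), 100 listeners = 200 ears
  cohort <- sample_cohort(cohort_spec(100, mean_dbhl = 10, sd_dbhl = 10,
                                      model = "logistic", seed = 2024))
  set.seed(2025)
  hits <- 0L; total <- 0L
  for (vl in cohort) {
    ag <- run_session(vl)
    df <- as.data.frame(ag)
    truth <- true_thresholds(vl)
    for (i in seq_len(nrow(df))) {
      if (df$no_response[i]) next
      total <- total + 1L
      err <- df$threshold_dbhl[i] -
        truth[df$ear[i], as.character(df$freq_hz[i])]
      if (abs(err) <= 5) hits <- hits + 1L
    }
  }
  expect_gte(total, 1100)
  expect_gte(hits / total, 0.95)
})
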