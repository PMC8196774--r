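test_that("step-model responses are an inclusive threshold boundary", {
  vl <- virtual_listener(rep(40, 6))
  expect_true(respond(vl, "right", 1000, level = 40))
  expect_false(respond(vl, "right", 1000, level = 39.9))
  expect_true(respond(vl, "left", 8000, level = 120))
  expect_error(respond(vl, "middle", 1000, 40), "no threshold")
})

test_that("empirical logistic response rates match the closed form within 0.02", {
  set.seed(101)
  vl <- virtual_listener(rep(30, 6), model = "logistic", slope = 2,
                         guess_rate = 0.01, lapse_rate = 0.01)
  for (level in c(10, 26, 28, 30, 32, 34, 50)) {
    p_hat <- mean(replicate(10000, respond(vl, "right", 2000, level)))
    p_true <- response_probability(vl, "right", 2000, level)
    expect_lt(abs(p_hat - p_true), 0.02)
  }
  # level = threshold with no guess/lapse: p = 0.5
  vl0 <- virtual_listener(rep(30, 6), model = "logistic", slope = 2,
                          guess_rate = 0, lapse_rate = 0)
  expect_equal(response_probability(vl0, "right", 1000, 30), 0.5)
  p_half <- mean(replicate(10000, respond(vl0, "right", 1000, 30)))
  expect_lt(abs(p_half - 0.5), 0.02)
  # far above threshold (10 scale units) with lapse 0: near certainty
  vl1 <- virtual_listener(rep(30, 6), model = "logistic", slope = 2,
                          guess_rate = 0.01, lapse_rate = 0)
  p_top <- mean(replicate(2000, respond(vl1, "right", 1000, 30 + 10 * 2)))
  expect_gte(p_top, 0.99)
})

test_that("cohort sampling is deterministic under seed and respects SD = 0", {
  spec0 <- cohort_spec(5, mean_dbhl = 10, sd_dbhl = 0, seed = 9)
  cohort <- sample_cohort(spec0)
  for (vl in cohort)
    expect_true(all(vl$thresholds$threshold_dbhl == 10))
  a <- sample_cohort(cohort_spec(8, seed = 123))
  b <- sample_cohort(cohort_spec(8, seed = 123))
  expect_identical(a, b)
  c2 <- sample_cohort(cohort_spec(8, seed = 124))
  expect_false(identical(a, c2))
  # a 20-listener batch yields 40 ears of rows
  tab <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(sample_cohort(cohort_spec(20, seed = 1)), tab)
  df <- read_cohort_table(tab)
  expect_equal(nrow(df), 20 * 2 * 6)
  expect_equal(length(unique(paste(df$listener_id, df$ear))), 40)
})

test_that("cohort moments track the spec within 3 standard errors", {
  spec <- cohort_spec(100, mean_dbhl = 20, sd_dbhl = 8, seed = 77)
  thr <- unlist(lapply(sample_cohort(spec), function(vl)
    vl$thresholds$threshold_dbhl))
  n <- length(thr)                      # 1200 draws
  se_mean <- 8 / sqrt(n)
  expect_lt(abs(mean(thr) - 20), 3 * se_mean)
  se_sd <- 8 / sqrt(2 * (n - 1))
  # 1 dB quantization inflates SD by ~1/12 variance; negligible vs 3 SE here
  expect_lt(abs(sd(thr) - 8), 3 * se_sd + 0.05)
})

test_that("thresholds are quantized to 1 dB and clamped to [-10, 120]", {
  thr <- unlist(lapply(sample_cohort(
    cohort_spec(50, mean_dbhl = -10, sd_dbhl = 15, seed = 5)),
    function(vl) vl$thresholds$threshold_dbhl))
  expect_true(all(thr == round(thr)))
  expect_true(all(thr >= -10 & thr <= 120))
  expect_true(any(thr == -10))  # clamp active at this mean/SD
})

test_that("device listeners shift measured thresholds by the RETSPL error", {
  vl <- virtual_listener(rep(10, 6))
  expect_identical(as_device_listener(vl, numeric(0))$thresholds,
                   vl$thresholds)
  dev <- as_device_listener(vl, c("250" = 10))
  expect_equal(run_track(response_fn(dev, "right", 250),
                         cfg_for(250))$threshold, 20)
  expect_equal(run_track(response_fn(dev, "right", 500),
                         cfg_for(500))$threshold, 10)
  down <- as_device_listener(vl, c("1000" = -15))
  expect_equal(run_track(response_fn(down, "left", 1000),
                         cfg_for(1000))$threshold, -5)
  expect_error(as_device_listener(vl, c("300" = 5)), "unknown")
})

test_that("device-listener shifts compose with run_track within one ascend step", {
  cohort <- sample_cohort(cohort_spec(6, mean_dbhl = 15, sd_dbhl = 6,
                                      seed = 31))
  for (delta in c(-10, -3, 6, 15)) {
    err <- stats::setNames(rep(delta, 6), as.character(test_frequencies()))
    for (vl in cohort[1:3]) {
      dev <- as_device_listener(vl, err)
      for (f in c(500, 4000)) {
        base <- run_track(response_fn(vl, "right", f), cfg_for(f))$threshold
        shifted <- run_track(response_fn(dev, "right", f),
                             cfg_for(f))$threshold
        expect_lte(abs((shifted - base) - delta), 5)
      }
    }
  }
})

test_that("listener invariants reject out-of-range parameters", {
  expect_error(virtual_listener(rep(10, 6), guess_rate = 0.2), "guess_rate")
  expect_error(virtual_listener(rep(10, 6), slope = 0), "slope")
  expect_error(virtual_listener(rep(130, 6)), "\\[-10, 120\\]")
})
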