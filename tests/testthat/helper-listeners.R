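# shared fixtures, built in code

# a step-function responder: hears iff level >= threshold
step_listener <- function(threshold) {
  force(threshold)
  function(level) level >= threshold
}

# staircase config with the per-frequency ceiling applied
cfg_for <- function(freq) staircase_config(ceiling = max_level_hl(freq))

# small deterministic paired dataset: audiometer = device + offset everywhere
flat_paired <- function(offset = 0, n_ears = 4, base = c(10, 15, 10, 5)) {
  aud <- rep_len(base, n_ears)
  paired_measurements(data.frame(
    ear_id = rep(seq_len(n_ears), each = 6),
    freq_hz = rep(test_frequencies(), n_ears),
    audiometer_dbhl = rep(aud, each = 6),
    device_dbhl = rep(aud - offset, each = 6)))
}

# published RETSPL reference rows, frozen
ER3A_ROW <- c("250" = 14.5, "500" = 6.0, "1000" = 0, "2000" = 2.5,
              "4000" = 0, "8000" = -3.5)
V1_ROW <- c("250" = 11.8, "500" = 9.5, "1000" = 6, "2000" = 2.3,
            "4000" = 6.7, "8000" = 16.2)
V2_ROW <- c("250" = 1.8, "500" = -5.5, "1000" = 1, "2000" = 7.3,
            "4000" = 13.7, "8000" = 13.7)
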