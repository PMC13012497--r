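test_that("cohort generation is deterministic and validates its config", {
  cfg <- sim_config(n_participants = 6L, n_electrodes = 6L, seed = 33L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$features, b$features)

  expect_error(sim_config(report_probabilities = c(
    CE = 0.5, rCEWR = 0.2, sCEWR = 0.2, CESP = 0.2, UNC = 0.1)),
    "sum to 1")
  expect_error(sim_config(participant_sd = -1), ">= 0")
  expect_error(sim_config(fixed_effects = c(bogus = 1)), "unknown")
})

test_that("zero participants yield a valid empty dataset", {
  coh <- generate_cohort(sim_config(n_participants = 0L, n_electrodes = 4L))
  expect_s3_class(coh, "cohort_dataset")
  expect_identical(nrow(coh$records), 0L)
  expect_identical(nrow(coh$features$ratio), 0L)
  expect_identical(ncol(coh$features$ratio), 4L)
})

test_that("study-scale defaults reproduce the design and report mix", {
  coh <- generate_cohort(sim_config(n_electrodes = 8L, seed = 2L))
  rec <- coh$records
  n <- nrow(rec)
  expect_identical(length(unique(rec$participant_id)), 44L)
  expect_true(all(rec$night %in% 1:4))
  expect_true(all(rec$time >= -1 & rec$time <= 7.5))
  expect_gt(n, 900); expect_lt(n, 1200)
  # multinomial check against the configured probabilities (3 SE slack)
  probs <- c(CE = 0.421875, CEWR = 0.35546875, NCE = 0.22265625)
  cnt <- table(factor(rec$report3, names(probs)))
  for (k in names(probs)) {
    se <- sqrt(n * probs[k] * (1 - probs[k]))
    expect_lt(abs(cnt[[k]] - n * probs[k]), 3 * se)
  }
  # participants nested in experiment
  nest <- tapply(rec$experiment, rec$participant_id,
                 function(e) length(unique(e)))
  expect_true(all(nest == 1L))
  # Likert ratings on scale
  expect_true(all(rec$sleep_depth %in% 1:5))
  expect_true(all(rec$sleepiness %in% 1:5))
  # log-ratio identity of the generated feature tables
  expect_lt(max(abs(coh$features$ratio -
                      (coh$features$gamma - coh$features$delta))), 1e-9)
})

test_that("report frequencies converge to the configured probabilities", {
  cfg <- sim_config(n_participants = 80L, n_nights = 4L,
                    awakenings_per_night = c(8L, 8L),
                    n_electrodes = 3L, seed = 91L)
  rec <- generate_cohort(cfg)$records
  p_hat <- prop.table(table(factor(rec$report5,
                                   names(cfg$report_probabilities))))
  n <- nrow(rec)
  for (k in names(cfg$report_probabilities)) {
    se <- sqrt(cfg$report_probabilities[k] *
                 (1 - cfg$report_probabilities[k]) / n)
    expect_lt(abs(p_hat[[k]] - cfg$report_probabilities[k]), 4 * se)
  }
})

test_that("null effect topography gives nominal channel-wise false positives", {
  # with no activation effect, ~5% of electrodes reach p < 0.05
  hits <- 0L; total <- 0L
  for (s in 1:50) {
    coh <- generate_cohort(sim_config(
      n_participants = 10L, n_electrodes = 8L,
      fixed_effects = c(depth_activation = 0), seed = 1000L + s))
    st <- channelwise_fit(coh$features$ratio, coh$records, "sleep_depth")
    hits <- hits + sum(st$p < 0.05, na.rm = TRUE)
    total <- total + sum(!is.na(st$p))
  }
  expect_gt(hits / total, 0.02)
  expect_lt(hits / total, 0.08)
})

test_that("injected cluster effects have the configured geometry", {
  sa <- grid_sensors(5L, 5L)
  co <- inject_cluster_effect(sa, "E013", radius = 0, amplitude = 2)
  expect_identical(sum(co != 0), 1L)
  expect_identical(unname(co[["E013"]]), 2)

  co_all <- inject_cluster_effect(sa, "E013", radius = 100, amplitude = 2)
  expect_true(all(co_all == 2))

  # brute-force distance check for an intermediate radius
  r <- 1.5
  co_mid <- inject_cluster_effect(sa, "E013", radius = r, amplitude = 1)
  pos <- as.matrix(sa[c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(pos, 2, pos[13, ])^2))
  expect_identical(unname(co_mid != 0), d <= r)

  expect_error(inject_cluster_effect(sa, "nope", 1, 1), "nope")
})

test_that("synthetic EEG segments honour closed-form band powers", {
  z <- generate_eeg_segment(c(delta = 0, gamma = 0), duration = 10,
                            fs = 128, seed = 1)
  expect_true(all(z$data == 0))

  s <- generate_eeg_segment(c(delta = 3), duration = 60, fs = 128, seed = 2)
  psd <- welch_psd(s)
  expect_equal(band_power(psd, band_definition("delta", 0.5, 4))[[1]],
               9 / 2, tolerance = 0.01)
  expect_lt(band_power(psd, band_definition("gamma", 25, 50))[[1]], 1e-6)

  wn <- generate_eeg_segment(c(delta = 0), duration = 120, fs = 128,
                             noise_sd = 1.5, seed = 3)
  tot <- pracma::trapz(welch_psd(wn)$freq, welch_psd(wn)$psd[1, ])
  expect_equal(tot, 1.5^2, tolerance = 0.1 * 1.5^2)

  expect_error(generate_eeg_segment(fs = 80), "100 Hz")
  expect_error(generate_eeg_segment(duration = 1.0001, fs = 128),
               "integral")
})
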