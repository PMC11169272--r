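test_that("R-peak detection matches ground truth on clean and noisy trains", {
  fr <- flat_recording(rr = 0.8, n_beats = 12)
  pk <- detect_r_peaks(fr$x, fr$fs)
  expect_length(pk, 12)
  err_ms <- abs((pk - 1) / fr$fs - fr$r_times) * 1000
  expect_lt(max(err_ms), 10)
  expect_identical(detect_r_peaks(rep(0, 5000), 500), integer(0))
  withr::with_seed(2, {
    noisy <- fr$x + rnorm(length(fr$x), sd = 20)
    expect_length(detect_r_peaks(noisy, fr$fs), 12)
  })
  expect_error(detect_r_peaks(rnorm(100), 500), "2 s")
})

test_that("delineation finds J points near truth and keeps fiducials ordered", {
  fr <- flat_recording(rr = 0.7, n_beats = 15, st_offset = -120)
  d <- delineate(fr$x, fr$fs)
  ok <- d$valid
  expect_gte(mean(ok), 0.8)
  j_err <- abs((d$j_point[ok] - 1) / fr$fs - fr$j_times[seq_len(nrow(d))][ok]) * 1000
  expect_gte(mean(j_err <= 12), 0.95)
  expect_true(all(d$q_onset[ok] < d$r_peak[ok] & d$r_peak[ok] < d$j_point[ok]))
  # beat truncated at the signal edge is flagged invalid, not an error
  rp <- round(fr$r_times[1:2] * fr$fs) + 1L
  edge <- delineate(fr$x[1:(rp[2] + 10)], fr$fs, r_peaks = rp)
  expect_false(tail(edge$valid, 1))
  expect_error(delineate(fr$x, fr$fs, integer(0)), "non-empty")
})

test_that("per-sequence ST depression recovers programmed offsets", {
  rec <- fixture_noiseless_recording()  # stress -150, recovery -60
  seqs <- build_sequences(rec, max_sequences = 10, seed = 7)
  ft <- purrr::map_dfr(seqs, st_depression_sequence)
  expect_true(all(ft$valid))
  expect_lt(abs(mean(ft$delta_stress) - 150), 5)
  expect_lt(abs(mean(ft$delta_rec) - 60), 5)
  # depression is positive when ST drops below the isoelectric line
  expect_true(all(ft$delta_stress > 0))
})

test_that("identical waveform in all three sub-segments gives zero deltas", {
  fr <- flat_recording(rr = 0.5, n_beats = 10)
  vals <- rep(fr$x[1:1000], 5)
  s <- structure(list(values = vals, boundaries = c(1000L, 4000L),
                      source_windows = c(pre = 0, stress = 10, rec = 20),
                      lead_id = "L1", patient_id = "T"),
                 class = "carpe_seq262")
  ft <- st_depression_sequence(s)
  expect_equal(ft$delta_stress, 0, tolerance = 1e-6)
  expect_equal(ft$delta_rec, 0, tolerance = 1e-6)
})

test_that("ST amplitude is read exactly 30 samples after the J point at 500 Hz", {
  fr <- flat_recording(rr = 0.8, n_beats = 13, st_offset = -100)
  vals <- fr$x[1:5000]
  d <- delineate(vals, 500)
  # spike one J+60ms sample in the stress sub-segment and watch st_stress move
  jj <- d$j_point[d$valid & d$j_point > 1000 & d$j_point + 30 <= 4000]
  ft0 <- st_depression_sequence(make_seq(vals), d)
  vals2 <- vals
  vals2[jj[1] + 30] <- vals2[jj[1] + 30] - 500
  ft1 <- st_depression_sequence(make_seq(vals2), d)
  n_stress <- sum(d$valid & d$j_point > 1000 & d$j_point + 30 <= 4000 &
                    d$q_onset > 1000)
  expect_gt(ft1$st_stress - ft0$st_stress, 0)  # deeper ST, larger depression
  # shifting any other sample leaves the measurement untouched
  vals3 <- vals
  vals3[jj[1] + 29] <- vals3[jj[1] + 29] - 500
  ft2 <- st_depression_sequence(make_seq(vals3), d)
  expect_equal(ft2$st_stress, ft0$st_stress, tolerance = 1e-9)
})

test_that("patient aggregation implements the four methods and their ordering", {
  d <- c(10, 20, 90)
  expect_equal(aggregate_patient(d, "min"), 10)
  expect_equal(aggregate_patient(d, "median"), 20)
  expect_equal(aggregate_patient(d, "max"), 90)
  expect_equal(aggregate_patient(d, "mean"), 40)
  expect_equal(aggregate_patient(42, "median"), 42)
  expect_error(aggregate_patient(numeric(0), "mean"), "no valid")
  withr::with_seed(11, {
    for (i in 1:20) {
      v <- rnorm(sample(1:12, 1), sd = 50)
      agg <- vapply(c("min", "median", "mean", "max"), aggregate_patient,
                    numeric(1), deltas = v)
      expect_true(agg["min"] <= agg["median"] && agg["median"] <= agg["max"])
      expect_true(agg["min"] <= agg["mean"] && agg["mean"] <= agg["max"])
    }
  })
})

test_that("ST parameter selection maximises AUPRC over the declared grid", {
  cohort <- fixture_signal_cohort()
  sel <- select_st_params(cohort, l_pr_grid = c(60, 80), methods = c("mean", "max"),
                          which_grid = "delta_stress", max_sequences = 4)
  expect_equal(nrow(sel$grid), 4)  # product of axis lengths
  expect_equal(sel$best$auprc, max(sel$grid$auprc))
  one <- select_st_params(cohort, l_pr_grid = 80, methods = "mean",
                          which_grid = "delta_stress", max_sequences = 4)
  expect_equal(nrow(one$grid), 1)
  expect_identical(one$best$method, "mean")
  # the depression statistic separates the classes on this cohort
  expect_gt(sel$best$auprc, 0.8)
})
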