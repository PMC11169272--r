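test_that("beat template realises the programmed ST offset exactly", {
  fs <- 500
  for (case in list(list(rr = 0.8, st = 0), list(rr = 0.8, st = -100),
                    list(rr = 0.5, st = -200), list(rr = 0.4, st = -100))) {
    b <- generate_beat(case$rr, case$st, fs)
    f <- b$fiducials
    pr_win <- (round((f$q_onset - 0.08) * fs) + 1):round(f$q_onset * fs)
    pr <- mean(b$waveform[pr_win])
    st <- b$waveform[round((f$j_point + 0.06) * fs) + 1]
    expect_lt(abs((st - pr) - case$st), 1)
  }
})

test_that("beat duration scales with the RR interval", {
  n1 <- length(generate_beat(0.8, 0, 500)$waveform)
  n2 <- length(generate_beat(0.4, 0, 500)$waveform)
  expect_equal(n1, 400)
  expect_equal(n2, n1 / 2)
  expect_equal(length(generate_beat(0.8, 0, 1000)$waveform), 800)
})

test_that("beat fiducials are strictly ordered and inputs validated", {
  b <- generate_beat(0.7, -80, 500)
  f <- b$fiducials
  expect_true(f$q_onset < f$r_peak && f$r_peak < f$j_point &&
                f$j_point < f$t_offset)
  expect_error(generate_beat(0.1, 0, 500), "rr_interval")
  expect_error(generate_beat(2.5, 0, 500), "rr_interval")
  expect_error(generate_beat(0.8, 0, 256), "fs")
})

test_that("assembled recordings have the programmed size, determinism and HR profile", {
  rec <- fixture_noiseless_recording()
  expect_equal(nrow(rec$signals), 240 * 500)
  # deterministic given seed
  rec2 <- tiny_recording()
  expect_identical(rec$signals, rec2$signals)
  expect_identical(rec$truth$r_peak_times, rec2$truth$r_peak_times)
  # per-minute HR from ground-truth R peaks peaks in the final stress minute
  hr <- rec$truth$hr_profile
  stress_minutes <- seq_len(floor(rec$phases$stress_end / 60))
  expect_equal(which.max(hr), max(stress_minutes))
  expect_error(assemble_recording(phase_durations = c(0.2, 100, 60)),
               "too short|positive")
  expect_error(assemble_recording(hr_ramp = c(120, 100)), "peak HR")
})

test_that("noiseless leads are scaled copies of the same source", {
  rec <- assemble_recording(phase_durations = c(20, 130, 40), n_leads = 3,
                            noise = list(wander = 0, broadband = 0, burst = 0),
                            seed = 9)
  s <- rec$truth$lead_scales
  expect_equal(rec$signals[, 2], rec$signals[, 1] * s[2] / s[1])
  expect_equal(rec$signals[, 3], rec$signals[, 1] * s[3] / s[1])
})

test_that("fCAD adjudication follows the SDS >= 2 / TID threshold rule", {
  expect_true(adjudicate_fcad(4, 1, 1.00, "dual"))
  expect_true(adjudicate_fcad(1, 0, 1.22, "dual"))
  expect_false(adjudicate_fcad(0, 0, 1.00, "single"))
  expect_true(adjudicate_fcad(0, 0, 1.12, "single"))
  expect_false(adjudicate_fcad(0, 0, 1.12, "dual"))
  expect_true(adjudicate_fcad(5, 3, 0.9, "single"))
  expect_false(adjudicate_fcad(4, 3, 0.9, "dual"))
  expect_error(adjudicate_fcad(1, 0, 1, "triple"), "protocol")
  expect_error(adjudicate_fcad(-1, 0, 1, "dual"))
})

test_that("sampled patients always satisfy the adjudication rule for their label", {
  for (s in 1:25) {
    lab <- s %% 2 == 0
    p <- sample_patient(lab, seed = s)
    expect_equal(adjudicate_fcad(p$sss, p$srs, p$tid, p$isotope_protocol), lab)
    expect_true(p$vas_pre >= 0 && p$vas_pre <= 1)
    expect_true(p$vas_post >= 0 && p$vas_post <= 1)
    expect_true(all(c(p$age, p$weight, p$height, p$hr_rest, p$sbp, p$dbp) > 0))
  }
})

test_that("CAD-history odds ratio is recovered over a large simulated cohort", {
  pts <- memo("patients10k", function() {
    generate_cohort(10000, prevalence = 0.329, seed = 13)$patients
  })
  tab <- table(history = pts$cad_history, fcad = pts$fcad)
  or <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
    (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
  expect_gt(or, 2.2)
  expect_lt(or, 3.2)
})

test_that("noise-free cardiologist score is a monotone readout of true risk", {
  cfg <- cohort_config(vas_noise_sd = 0, vas_tail_shrink = 0.35)
  pts <- generate_cohort(300, prevalence = 0.4, seed = 3, config = cfg)$patients
  expect_true(all(diff(pts$vas_post[order(pts$true_risk)]) >= 0))
  expect_gt(metric_auroc(pts$vas_post, pts$fcad), 0.9)
})

test_that("cohorts have exact stratified label counts and are reproducible", {
  expect_equal(nrow(generate_cohort(0)$patients), 0)
  co <- generate_cohort(100, prevalence = 0.28, seed = 5)
  expect_equal(sum(co$patients$fcad), 28)
  co2 <- generate_cohort(100, prevalence = 0.28, seed = 5)
  expect_identical(co$patients, co2$patients)
  co3 <- generate_cohort(100, prevalence = 0.28, seed = 6)
  expect_false(identical(co$patients, co3$patients))
})

test_that("recordings round-trip through the text record format", {
  rec <- assemble_recording(phase_durations = c(20, 130, 40), seed = 31)
  dir <- withr::local_tempdir()
  write_recording(rec, dir, "demo")
  back <- read_recording(dir, "demo")
  expect_equal(back$fs, rec$fs)
  expect_equal(back$phases$stress_end, rec$phases$stress_end)
  expect_equal(unname(back$signals[, 1]), unname(round(rec$signals[, 1], 3)),
               tolerance = 1e-9)
  expect_equal(back$truth$r_peak_times, rec$truth$r_peak_times,
               tolerance = 1e-6)
  pts <- generate_cohort(5, prevalence = 0.4, seed = 2)$patients
  pth <- file.path(dir, "patients.csv")
  write_patients(pts, pth)
  back_pts <- read_patients(pth)
  expect_equal(back_pts$fcad, pts$fcad)
  expect_equal(back_pts$sss, pts$sss)
})
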