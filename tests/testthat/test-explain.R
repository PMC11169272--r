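test_that("permutation attributions are additive and match linear closed form", {
  withr::with_seed(14, {
    p <- 6
    beta <- rnorm(p)
    f <- function(mat) drop(mat %*% beta) + 2
    bg <- matrix(rnorm(30 * p), 30, p)
    x <- rnorm(p)
    res <- attribute(f, x, bg, n_perm = 3, seed = 1)
    # additivity is exact by telescoping
    expect_equal(res$baseline + sum(res$attributions), res$prediction,
                 tolerance = 1e-10)
    # linear model: Shapley value is beta_j * (x_j - mean(background_j))
    expect_equal(unname(res$attributions), beta * (x - colMeans(bg)),
                 tolerance = 1e-6)
  })
})

test_that("an ignored feature receives zero attribution", {
  withr::with_seed(15, {
    f <- function(mat) plogis(mat[, 1] - 0.5 * mat[, 3])
    bg <- matrix(rnorm(20 * 4), 20, 4)
    res <- attribute(f, rnorm(4), bg, n_perm = 5, seed = 2)
    expect_lt(abs(res$attributions[2]), 1e-3)
    expect_lt(abs(res$attributions[4]), 1e-3)
  })
})

test_that("grouped attribution conserves totals for the network explainer", {
  fx <- fixture_mtl_model()
  cohort <- fx$cohort
  id <- cohort$patients$patient_id[2]
  seq1 <- build_sequences(cohort$recordings[[id]], max_sequences = 1, seed = 5)[[1]]
  expl <- attribute_mtl(fx$model, seq1, cohort$patients[2, ], fx$data,
                        window = 500, n_perm = 2, seed = 3)
  total <- sum(expl$ecg) + sum(expl$clinical)
  expect_equal(expl$baseline + total, expl$prediction, tolerance = 1e-3)
})

test_that("segment aggregation conserves attribution mass", {
  fr <- flat_recording(rr = 0.8, n_beats = 13, st_offset = -100)
  vals <- fr$x[1:5000]
  d <- delineate(vals, 500)
  withr::with_seed(16, {
    attr_vec <- rnorm(5000, sd = 0.01)
    sa <- aggregate_segments(attr_vec, d)
    expect_equal(sum(sa$table$value) + sa$other, sum(attr_vec),
                 tolerance = 1e-10)
    expect_true(all(sa$table$phase %in% c("pre", "stress", "rec")))
  })
  # attribution mass placed only inside ST windows lands in the ST bucket
  st_attr <- numeric(5000)
  ok <- d[d$valid, ]
  for (i in seq_len(nrow(ok))) {
    st_attr[ok$j_point[i]:(ok$j_point[i] + 40)] <- 0.05
  }
  sa2 <- aggregate_segments(st_attr, d)
  st_share <- sum(sa2$table$value[sa2$table$segment == "st_segment"]) /
    (sum(sa2$table$value) + sa2$other)
  expect_gte(st_share, 0.99)
  expect_error(aggregate_segments(st_attr, NULL), "delineation")
})

test_that("salient-wave extraction follows the threshold rules and bands", {
  fr <- flat_recording(rr = 0.8, n_beats = 13, st_offset = -100)
  vals <- fr$x[1:5000]
  d <- delineate(vals, 500)
  s <- make_seq(vals)
  # nothing passes the thresholds -> empty
  sa0 <- aggregate_segments(numeric(5000), d)
  expect_equal(nrow(extract_salient_waves(s, sa0, d, score = 0.95)), 0)
  # exactly 3 beats exceed +0.25 on the ST segment of a high-score patient
  ok <- d[d$valid, ]
  st_attr <- numeric(5000)
  for (i in 2:4) st_attr[ok$j_point[i]:(ok$j_point[i] + 30)] <- 0.02
  sa <- aggregate_segments(st_attr, d)
  expect_equal(sum(sa$table$value[sa$table$segment == "st_segment"] >= 0.25), 3)
  waves <- extract_salient_waves(s, sa, d, score = 0.9)
  expect_equal(nrow(waves), 3)
  expect_true(all(waves$rule == "st_high"))
  # wave boundaries ordered and inside one sub-segment
  edges <- c(0, 1000, 4000, 5000)
  seg_of <- findInterval(waves$start - 1, edges, rightmost.closed = TRUE)
  expect_true(all(seg_of == findInterval(waves$end - 1, edges,
                                         rightmost.closed = TRUE)))
  expect_true(all(waves$start < waves$end))
  # the same attribution in a mid-band patient triggers nothing
  expect_equal(nrow(extract_salient_waves(s, sa, d, score = 0.5)), 0)
  # QRS rule fires only for low-probability patients
  qrs_attr <- numeric(5000)
  qrs_attr[ok$q_onset[5]:(ok$j_point[5] - 1)] <- -0.02
  saq <- aggregate_segments(qrs_attr, d)
  expect_gte(nrow(extract_salient_waves(s, saq, d, score = 0.05)), 1)
  expect_equal(nrow(extract_salient_waves(s, saq, d, score = 0.95)), 0)
})
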