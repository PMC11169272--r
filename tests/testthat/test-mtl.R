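test_that("the network specification exposes four heads and validates inputs", {
  spec <- build_mtl(mtl_config(), n_leads = 1)
  expect_length(spec$heads, 4)
  expect_equal(spec$head_types[["fcad"]], "binary")
  expect_error(build_mtl(mtl_config(), n_clinical = 7), "8 clinical")
  expect_error(build_mtl(mtl_config(), seq_len = 4000), "5000")
  expect_error(mtl_config(task_weights = c(fcad = 0, sss = 1, srs = 1, pharm = 1)),
               "positive")
  expect_error(mtl_config(lr = -1), "learning rate")
})

test_that("a forward pass returns four outputs of batch length", {
  cfg <- mtl_config(n_residual_blocks = 2, channel_width = 4)
  spec <- build_mtl(cfg, n_leads = 1)
  params <- carpe:::mtl_init(spec, seed = 1)
  B <- 3
  x <- array(rnorm(5000 * B), dim = c(5000, 1, B))
  clin <- matrix(rnorm(8 * B), 8, B)
  fwd <- carpe:::mtl_forward(params, spec, x, clin)
  expect_named(fwd$outputs, c("fcad", "sss", "srs", "pharm"))
  for (o in fwd$outputs) expect_length(o, B)
  expect_true(all(fwd$outputs$fcad >= 0 & fwd$outputs$fcad <= 1))
})

test_that("the multi-task loss combines per-task losses linearly", {
  tg <- list(fcad = c(1, 0), sss = c(2, -1), srs = c(0, 1), pharm = c(0, 1))
  perfect <- list(fcad = c(1, 0), sss = c(2, -1), srs = c(0, 1), pharm = c(0, 1))
  w <- c(fcad = 1, sss = 1, srs = 1, pharm = 1)
  expect_lt(mtl_loss(perfect, tg, w), 1e-10)
  # hand-computed BCE: single sample, target 1 predicted 0.5, main task only
  out1 <- list(fcad = 0.5, sss = 0, srs = 0, pharm = 0)
  tg1 <- list(fcad = 1, sss = 0, srs = 0, pharm = 0)
  expect_equal(mtl_loss(out1, tg1, c(fcad = 1, sss = 0, srs = 0, pharm = 0)),
               -log(0.5), tolerance = 1e-9)
  out <- list(fcad = c(0.8, 0.3), sss = c(1, 0), srs = c(0.5, 2), pharm = c(0.1, 0.9))
  expect_equal(mtl_loss(out, tg, 2 * w), 2 * mtl_loss(out, tg, w))
  # main-task-only weights reduce the loss to the fCAD BCE alone
  w0 <- c(fcad = 1, sss = 0, srs = 0, pharm = 0)
  bce <- -mean(tg$fcad * log(out$fcad) + (1 - tg$fcad) * log(1 - out$fcad))
  expect_equal(mtl_loss(out, tg, w0), bce)
  expect_error(mtl_loss(out, list(fcad = 1, sss = 0, srs = 0, pharm = 0), w),
               "mismatch")
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- mtl_config(n_residual_blocks = 2, channel_width = 4, kernel = 5,
                    stem_kernel = 7,
                    task_weights = c(fcad = 1, sss = 0.7, srs = 0.3, pharm = 0.5))
  spec <- build_mtl(cfg, n_leads = 1)
  withr::with_seed(3, {
    params <- carpe:::mtl_init(spec, seed = 5)
    # heads are zero-initialised; give them mass so gradients reach the trunk
    for (h in spec$heads) {
      params[[paste0("head_", h, "_w")]][] <- rnorm(spec$feat_dim, 0, 0.3)
    }
    B <- 2
    x <- array(rnorm(5000 * B), dim = c(5000, 1, B))
    clin <- matrix(rnorm(8 * B), 8, B)
    tg <- list(fcad = c(1, 0), sss = rnorm(2), srs = rnorm(2), pharm = c(0, 1))
    fwd <- carpe:::mtl_forward(params, spec, x, clin, keep_cache = TRUE)
    L0 <- mtl_loss(fwd$outputs, tg, cfg$task_weights)
    g <- carpe:::mtl_backward(params, spec, fwd,
                              carpe:::head_grads(fwd, tg, cfg$task_weights))
    eps <- 1e-5
    for (nm in c("stem_w", "blk1_w1", "blk2_w2", "clin_w1", "head_fcad_w",
                 "head_sss_w", "blk1_b2")) {
      k <- sample(length(params[[nm]]), 1)
      p2 <- params
      p2[[nm]][k] <- p2[[nm]][k] + eps
      f2 <- carpe:::mtl_forward(p2, spec, x, clin)
      num <- (mtl_loss(f2$outputs, tg, cfg$task_weights) - L0) / eps
      expect_equal(g[[nm]][k], num, tolerance = 1e-3)
    }
  })
})

test_that("training is deterministic given the seed", {
  fx <- fixture_mtl_model()
  cfg <- mtl_config(n_residual_blocks = 2, channel_width = 8, epochs = 1,
                    seed = 5)
  m1 <- train_mtl(fx$data, cfg)
  m2 <- train_mtl(fx$data, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("per-patient prediction averages the main head over sequences", {
  fx <- fixture_mtl_model()
  model <- fx$model
  cohort <- fx$cohort
  id <- cohort$patients$patient_id[1]
  seqs <- build_sequences(cohort$recordings[[id]], max_sequences = 3, seed = 5)
  p <- predict_patient(model, seqs, cohort$patients[1, ])
  singles <- vapply(seqs, function(s) {
    predict_patient(model, list(s), cohort$patients[1, ])
  }, numeric(1))
  expect_equal(p, mean(singles), tolerance = 1e-9)
  expect_equal(predict_patient(model, seqs[1], cohort$patients[1, ]), singles[1])
  # invariant to sequence ordering
  expect_equal(predict_patient(model, rev(seqs), cohort$patients[1, ]), p)
  expect_error(predict_patient(model, list(), cohort$patients[1, ]), "sequence")
  expect_true(all(singles >= 0 & singles <= 1))
})

test_that("the selection grid enumerates the full Cartesian product", {
  g <- enumerate_lead_grid()
  expect_equal(nrow(g), 117)
  expect_equal(nrow(enumerate_lead_grid("lead_1", "none", 0.001)), 1)
  g2 <- enumerate_lead_grid(c("a", "b"), c("x", "y", "z"), c(1, 2))
  expect_equal(nrow(g2), 2 * 3 * 2)
  expect_equal(nrow(dplyr::distinct(g2)), 12)
})

test_that("grid search ranks configurations by mean validation AUPRC", {
  fx <- fixture_mtl_model()
  dat <- fx$data
  ids <- unique(dat$patient_id)
  tr_ids <- ids[seq_len(24)]
  sel_tr <- dat$patient_id %in% tr_ids
  subset_data <- function(keep) {
    structure(list(x = dat$x[, , keep, drop = FALSE],
                   clin = dat$clin[, keep, drop = FALSE],
                   targets = lapply(dat$targets, `[`, keep),
                   patient_id = dat$patient_id[keep]), class = "mtl_data")
  }
  splits <- list(list(train = subset_data(sel_tr), val = subset_data(!sel_tr)))
  gs <- grid_search_mtl(splits,
                        weight_grid = list(sss = c(0, 0.5), srs = 0, pharm = 0),
                        lr_grid = 0.003,
                        base_config = mtl_config(n_residual_blocks = 2,
                                                 channel_width = 8, epochs = 1,
                                                 seed = 5))
  expect_equal(nrow(gs$table), 2)
  expect_equal(gs$best$auprc, max(gs$table$auprc))
})
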