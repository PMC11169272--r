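#' Configuration for the multi-task ECG network
#'
#' The network couples a residual 1-D convolutional encoder for the 2-6-2
#' ECG sequence with a 2-layer feed-forward encoder for the eight clinical
#' variables; their concatenated representation feeds four heads — the main
#' fCAD task (binary), two auxiliary perfusion-score regressions (summed
#' stress and rest score) and an auxiliary pharmacological-support task
#' (binary). Auxiliary tasks act as domain-specific inductive biases that
#' regularise the main task.
#'
#' Defaults are the scaled-down desk-scale architecture (4 residual blocks,
#' 16 channels); a deeper full-scale encoder is a matter of configuration,
#' not code. The learning-rate grid used in selection is
#' `c(0.01, 0.001, 0.0001)`.
#'
#' @param task_weights Named non-negative weights `c(fcad, sss, srs, pharm)`;
#'   `fcad` must be positive.
#' @param lr Learning rate (Adam).
#' @param n_residual_blocks Number of residual blocks (each downsamples x4).
#' @param channel_width Convolutional channel count.
#' @param kernel,stem_kernel Convolution kernel lengths (samples).
#' @param epochs,batch_size Training schedule.
#' @param seed Integer seed controlling initialisation and data order.
#' @return An `mtl_config` list.
#' @export
mtl_config <- function(task_weights = c(fcad = 1, sss = 0.5, srs = 0.5, pharm = 0.25),
                       lr = 0.001, n_residual_blocks = 4, channel_width = 16,
                       kernel = 9, stem_kernel = 17, epochs = 2,
                       batch_size = 16, seed = 1) {
  cfg <- list(task_weights = task_weights, lr = lr,
              n_residual_blocks = n_residual_blocks,
              channel_width = channel_width, kernel = kernel,
              stem_kernel = stem_kernel, epochs = epochs,
              batch_size = batch_size, seed = seed,
              clinical_encoder_layers = 2)
  validate_mtl_config(cfg)
  cfg
}

validate_mtl_config <- function(cfg) {
  w <- cfg$task_weights
  if (!all(c("fcad", "sss", "srs", "pharm") %in% names(w))) {
    stopf("task_weights must name fcad, sss, srs, pharm")
  }
  if (any(!is.finite(w)) || any(w < 0)) stopf("task weights must be finite and >= 0")
  if (w[["fcad"]] <= 0) stopf("the main-task weight w_fcad must be positive")
  if (cfg$lr <= 0) stopf("learning rate must be positive")
  if (cfg$clinical_encoder_layers != 2) stopf("clinical encoder has exactly 2 layers")
  invisible(cfg)
}

#' Build the multi-task network specification
#'
#' @param config An [mtl_config()].
#' @param n_leads Number of ECG input channels.
#' @param n_clinical Number of clinical variables; must be 8.
#' @param seq_len Input sequence length; must be 5000.
#' @return An `mtl_spec` describing every layer shape; `$heads` always has
#'   length 4.
#' @export
build_mtl <- function(config = mtl_config(), n_leads = 1, n_clinical = 8,
                      seq_len = 5000) {
  validate_mtl_config(config)
  if (n_clinical != 8) stopf("the network takes exactly 8 clinical variables")
  if (seq_len != 5000) stopf("input sequence length must be 5000")
  C <- config$channel_width
  lens <- seq_len
  lens <- c(lens, floor((lens + 2 * ((config$stem_kernel - 1) %/% 2) -
                           config$stem_kernel) / 4) + 1)
  for (i in seq_len(config$n_residual_blocks)) {
    lens <- c(lens, floor((tail(lens, 1) - 1) / 4) + 1)
  }
  structure(list(
    n_leads = n_leads, n_clinical = n_clinical, seq_len = seq_len,
    channels = C, n_blocks = config$n_residual_blocks,
    kernel = config$kernel, stem_kernel = config$stem_kernel,
    pad = (config$kernel - 1) %/% 2, stem_pad = (config$stem_kernel - 1) %/% 2,
    lens = lens, feat_dim = 2 * C,
    heads = c("fcad", "sss", "srs", "pharm"),
    head_types = c(fcad = "binary", sss = "regression",
                   srs = "regression", pharm = "binary")
  ), class = "mtl_spec")
}

relu <- function(a) { a[a < 0] <- 0; a }

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

mtl_init <- function(spec, seed = 1) {
  with_seed(seed, {
    C <- spec$channels
    p <- list(
      stem_w = he_init(c(spec$stem_kernel, spec$n_leads, C),
                       spec$stem_kernel * spec$n_leads),
      stem_b = numeric(C)
    )
    for (i in seq_len(spec$n_blocks)) {
      p[[paste0("blk", i, "_w1")]] <- he_init(c(spec$kernel, C, C), spec$kernel * C)
      p[[paste0("blk", i, "_b1")]] <- numeric(C)
      p[[paste0("blk", i, "_w2")]] <- he_init(c(spec$kernel, C, C), spec$kernel * C)
      p[[paste0("blk", i, "_b2")]] <- numeric(C)
    }
    p$clin_w1 <- matrix(rnorm(C * spec$n_clinical, 0, sqrt(2 / spec$n_clinical)),
                        C, spec$n_clinical)
    p$clin_b1 <- numeric(C)
    p$clin_w2 <- matrix(rnorm(C * C, 0, sqrt(2 / C)), C, C)
    p$clin_b2 <- numeric(C)
    for (h in spec$heads) {
      # zero-initialised heads: the untrained network predicts a constant,
      # so scores carry no accidental input tilt before any label is seen
      p[[paste0("head_", h, "_w")]] <- matrix(0, 1, spec$feat_dim)
      p[[paste0("head_", h, "_b")]] <- 0
    }
    p
  })
}

# Forward pass. x: (L, Cin, B) array in model input units; clin: (8, B).
# The concatenated representation is layer-normalised per sample (no affine
# parameters) and then mean-centred across the batch before the heads.
# Layer norm equalises feature magnitude across patients; batch centring
# removes the nonzero feature mean that zero-initialised heads would
# otherwise accumulate as a deterministic drift direction proportional to
# (base rate - 1/2) x E[features]. Both are required for scores on
# label-free (permuted) data to stay untilted. At inference the stored
# training means are used; centring there only shifts every logit by the
# same constant, so rankings are unaffected.
mtl_forward <- function(params, spec, x, clin, keep_cache = FALSE,
                        feat_mu = NULL) {
  cache <- if (keep_cache) list(x = x, clin = clin) else NULL
  h_pre <- conv1d_fw(x, dim(x), params$stem_w, dim(params$stem_w),
                     params$stem_b, 4L, spec$stem_pad)
  h <- relu(h_pre)
  if (keep_cache) { cache$stem_pre <- h_pre; cache$stem <- h }
  for (i in seq_len(spec$n_blocks)) {
    w1 <- params[[paste0("blk", i, "_w1")]]
    w2 <- params[[paste0("blk", i, "_w2")]]
    a1 <- conv1d_fw(h, dim(h), w1, dim(w1),
                    params[[paste0("blk", i, "_b1")]], 4L, spec$pad)
    a1r <- relu(a1)
    a2 <- conv1d_fw(a1r, dim(a1r), w2, dim(w2),
                    params[[paste0("blk", i, "_b2")]], 1L, spec$pad)
    skip_idx <- (seq_len(dim(a2)[1]) - 1L) * 4L + 1L
    s <- a2 + h[skip_idx, , , drop = FALSE]
    out <- relu(s)
    if (keep_cache) {
      cache[[paste0("b", i)]] <- list(in_ = h, a1 = a1, a1r = a1r,
                                      s = s, skip_idx = skip_idx)
    }
    h <- out
  }
  gap <- colMeans(h, dims = 1)           # (C, B)
  if (is.null(dim(gap))) gap <- matrix(gap, ncol = dim(x)[3])
  z1 <- params$clin_w1 %*% clin + params$clin_b1
  z1r <- relu(z1)
  z2 <- params$clin_w2 %*% z1r + params$clin_b2
  feat_raw <- rbind(gap, z2)             # (2C, B)
  mu <- colMeans(feat_raw)
  xc <- sweep(feat_raw, 2, mu)
  sig <- sqrt(colMeans(xc^2) + 1e-6)
  feat_ln <- sweep(xc, 2, sig, "/")      # per-sample layer norm
  centre <- if (is.null(feat_mu)) rowMeans(feat_ln) else feat_mu
  feat <- feat_ln - centre
  logits <- lapply(spec$heads, function(hd) {
    drop(params[[paste0("head_", hd, "_w")]] %*% feat +
           params[[paste0("head_", hd, "_b")]])
  })
  names(logits) <- spec$heads
  if (keep_cache) {
    cache$last <- h; cache$gap_len <- dim(h)[1]
    cache$z1 <- z1; cache$z1r <- z1r
    cache$feat <- feat; cache$feat_ln <- feat_ln
    cache$ln_sig <- sig
    cache$batch_centred <- is.null(feat_mu)
  }
  out <- list(
    fcad = plogis(logits$fcad), sss = logits$sss, srs = logits$srs,
    pharm = plogis(logits$pharm)
  )
  list(outputs = out, logits = logits, cache = cache)
}

#' Multi-task loss
#'
#' `loss = w_fcad * BCE(fcad) + w_sss * MSE(sss) + w_srs * MSE(srs) +
#' w_pharm * BCE(pharm)`; each task has its own loss function, combined by
#' the non-negative task weights.
#'
#' @param outputs Named list of head outputs (`fcad`/`pharm` probabilities,
#'   `sss`/`srs` regression predictions), each length-B.
#' @param targets Named list of targets aligned with `outputs`.
#' @param task_weights Named weights `c(fcad, sss, srs, pharm)`.
#' @return Non-negative scalar.
#' @export
mtl_loss <- function(outputs, targets, task_weights) {
  for (nm in c("fcad", "sss", "srs", "pharm")) {
    if (length(outputs[[nm]]) != length(targets[[nm]])) {
      stopf("output/target length mismatch for head '%s'", nm)
    }
  }
  bce <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  mse <- function(p, y) mean((p - y)^2)
  w <- task_weights
  w[["fcad"]] * bce(outputs$fcad, targets$fcad) +
    w[["sss"]] * mse(outputs$sss, targets$sss) +
    w[["srs"]] * mse(outputs$srs, targets$srs) +
    w[["pharm"]] * bce(outputs$pharm, targets$pharm)
}

# Gradients of mtl_loss w.r.t. head logits/predictions, per sample (1/B inside).
head_grads <- function(fwd, targets, w) {
  B <- length(fwd$outputs$fcad)
  list(
    fcad = w[["fcad"]] * (fwd$outputs$fcad - targets$fcad) / B,
    sss = w[["sss"]] * 2 * (fwd$outputs$sss - targets$sss) / B,
    srs = w[["srs"]] * 2 * (fwd$outputs$srs - targets$srs) / B,
    pharm = w[["pharm"]] * (fwd$outputs$pharm - targets$pharm) / B
  )
}

mtl_backward <- function(params, spec, fwd, grads_head) {
  cache <- fwd$cache
  g <- list()
  feat <- cache$feat
  d_feat <- matrix(0, nrow(feat), ncol(feat))
  for (hd in spec$heads) {
    gh <- matrix(grads_head[[hd]], nrow = 1)
    wname <- paste0("head_", hd, "_w")
    g[[wname]] <- gh %*% t(feat)
    g[[paste0("head_", hd, "_b")]] <- sum(gh)
    d_feat <- d_feat + t(params[[wname]]) %*% gh
  }
  if (isTRUE(cache$batch_centred)) {
    # backward of batch-mean centring: project out the per-feature mean
    d_feat <- d_feat - rowMeans(d_feat)
  }
  # layer-norm backward (per sample/column): with y = (x - mu)/sig,
  # dx = (dy - mean(dy) - y * mean(dy * y)) / sig
  y <- cache$feat_ln
  d_feat <- sweep(d_feat, 2, colMeans(d_feat)) -
    sweep(y, 2, colMeans(d_feat * y), "*")
  d_feat <- sweep(d_feat, 2, cache$ln_sig, "/")
  C <- spec$channels
  d_gap <- d_feat[seq_len(C), , drop = FALSE]
  d_z2 <- d_feat[(C + 1):(2 * C), , drop = FALSE]
  g$clin_w2 <- d_z2 %*% t(cache$z1r)
  g$clin_b2 <- rowSums(d_z2)
  d_z1 <- (t(params$clin_w2) %*% d_z2) * (cache$z1 > 0)
  g$clin_w1 <- d_z1 %*% t(cache$clin)
  g$clin_b1 <- rowSums(d_z1)

  L5 <- cache$gap_len
  B <- ncol(feat)
  dh <- array(rep(as.numeric(d_gap / L5), each = L5), dim = c(L5, C, B))
  dh <- dh * (cache$last > 0)
  for (i in rev(seq_len(spec$n_blocks))) {
    bc <- cache[[paste0("b", i)]]
    w1 <- params[[paste0("blk", i, "_w1")]]
    w2 <- params[[paste0("blk", i, "_w2")]]
    d_s <- dh
    bw2 <- conv1d_bw(bc$a1r, dim(bc$a1r), w2, dim(w2), d_s, 1L, spec$pad)
    g[[paste0("blk", i, "_w2")]] <- bw2$dw
    g[[paste0("blk", i, "_b2")]] <- bw2$db
    d_a1 <- bw2$dx * (bc$a1 > 0)
    bw1 <- conv1d_bw(bc$in_, dim(bc$in_), w1, dim(w1), d_a1, 4L, spec$pad)
    g[[paste0("blk", i, "_w1")]] <- bw1$dw
    g[[paste0("blk", i, "_b1")]] <- bw1$db
    d_in <- bw1$dx
    d_in[bc$skip_idx, , ] <- d_in[bc$skip_idx, , , drop = FALSE] + d_s
    dh <- d_in
    if (i > 1) {
      prev <- cache[[paste0("b", i - 1)]]
      dh <- dh * (prev$s > 0)
    } else {
      dh <- dh * (cache$stem_pre > 0)
    }
  }
  bw0 <- conv1d_bw(cache$x, dim(cache$x), params$stem_w, dim(params$stem_w),
                   dh, 4L, spec$stem_pad)
  g$stem_w <- bw0$dw
  g$stem_b <- bw0$db
  g
}
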