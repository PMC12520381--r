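set.seed(20)
xin2 <- array(runif(41 * 41 * 2 * 3), c(41, 41, 2, 3))
xin1 <- xin2[, , 1, , drop = FALSE]
yt <- array(runif(41 * 41 * 2 * 3), c(41, 41, 2, 3))
ns <- asNamespace("TAAinvert")

tinyModels <- function() list(
  unet = buildUNet(2, width = 8, groups = 2, blocks = "single", seed = 3),
  cnn_deeponet = buildCNNDeepONet(2, conv_channels = c(4L, 8L, 8L),
                                  dense_hidden = 32L, p = 16L,
                                  trunk_width = 16L, seed = 3),
  fnn_deeponet = buildFNNDeepONet(2, hidden = c(24L, 24L), p = 16L,
                                  trunk_width = 16L, seed = 3),
  lno = buildLNO(2, layers = 2, width = 6, modes = 4, seed = 3))

test_that("every architecture maps map batches to two finite insult fields", {
  for (m in tinyModels()) {
    out <- ns$modelForward(m, xin2, keep_cache = FALSE)
    expect_equal(dim(out$y), c(41, 41, 2, 3))
    expect_true(all(is.finite(out$y)))
  }
  ## 1-channel variants simply omit the distensibility input path
  m1 <- buildUNet(1, width = 8, groups = 2, blocks = "single", seed = 3)
  expect_equal(dim(ns$modelForward(m1, xin1, FALSE)$y), c(41, 41, 2, 3))
  expect_error(buildUNet(3), "channels")
  expect_error(buildCNNDeepONet(2, p = 15L), "p")
  expect_error(buildLNO(2, modes = 25L), "Nyquist")
})

test_that("analytic gradients match finite differences for all architectures", {
  ms <- tinyModels()
  ## max-pooling makes the loss piecewise smooth: early-layer probes can
  ## cross an argmax kink inside the difference interval, so the pooled
  ## architectures get a correspondingly looser bound
  expect_lt(gradCheckWorst(ms$unet, xin2, yt), 2e-2)
  expect_lt(gradCheckWorst(ms$cnn_deeponet, xin2, yt, loss = "mse"), 1e-2)
  expect_lt(gradCheckWorst(ms$fnn_deeponet, xin2, yt, loss = "mse"), 1e-4)
  expect_lt(gradCheckWorst(ms$lno, xin2, yt), 1e-4)
})

test_that("DeepONet heads are dot products with split embeddings", {
  m <- tinyModels()$cnn_deeponet
  ## zeroed branch output and zero bias give identically zero fields
  m@params$br_d2_W[] <- 0
  m@params$br_d2_b[] <- 0
  m@params$head_b[] <- 0
  out <- ns$modelForward(m, xin2, FALSE)
  expect_equal(max(abs(out$y)), 0)
  ## swapping the two half-embeddings (branch, trunk, biases) swaps the heads
  m2 <- tinyModels()$fnn_deeponet
  h <- m2@spec$p %/% 2L
  sw <- c((h + 1):(2 * h), 1:h)
  m3 <- m2
  m3@params$br_d3_W <- m2@params$br_d3_W[, sw]
  m3@params$br_d3_b <- m2@params$br_d3_b[sw]
  m3@params$tr_3_W <- m2@params$tr_3_W[, sw]
  m3@params$tr_3_b <- m2@params$tr_3_b[sw]
  m3@params$head_b <- m2@params$head_b[2:1]
  y2 <- ns$modelForward(m2, xin2, FALSE)$y
  y3 <- ns$modelForward(m3, xin2, FALSE)$y
  expect_equal(y3[, , 1, ], y2[, , 2, ])
  expect_equal(y3[, , 2, ], y2[, , 1, ])
})

test_that("DeepONet predictions follow the trunk coordinates", {
  ## evaluating the trunk at permuted coordinates permutes the predictions
  m <- tinyModels()$fnn_deeponet
  co <- m@spec$coords
  set.seed(4)
  perm <- sample(nrow(co))
  y0 <- ns$deeponetForward(m@params, xin2, m@spec, FALSE)$y
  yp <- ns$deeponetForward(m@params, xin2, m@spec, FALSE,
                           coords = co[perm, ])$y
  for (hch in 1:2) {
    flat0 <- matrix(y0[, , hch, ], 41 * 41, 3)
    flatp <- matrix(yp[, , hch, ], 41 * 41, 3)
    expect_equal(flatp, flat0[perm, ])
  }
})

test_that("default UNet lands near the publication parameter count", {
  m <- buildUNet(2)
  expect_gte(nParameters(m), 1.5e6)
  expect_lte(nParameters(m), 2.5e6)
})

test_that("Laplace layer reduces to its closed-form pole-residue response", {
  ## single channel, single pole, single-mode cosine input: compare against
  ## the directly summed steady-state + transient response
  H <- 41
  x <- (0:(H - 1)) / H
  v <- array(cos(2 * pi * x), c(H, 1, 1, 1))
  rho <- 0.3; nu <- 2.2
  beta <- array(c(0.7), c(1, 1, 1))
  out <- ns$axisTransformF(v, rho, nu, beta + 0i, modes = 3L)
  ## independent double-loop oracle
  gam <- complex(real = -log1p(exp(0.3)), imaginary = 2.2)
  A <- fft(cos(2 * pi * x)) / H
  u <- complex(length.out = H)
  for (m in 0:2) {
    a <- A[m + 1]
    w <- 2i * pi * m
    u <- u + (0.7 / (w - gam)) * a * exp(w * x) +
      0.7 * (a / (gam - w)) * exp(gam * x)
  }
  expect_equal(as.vector(out$y), Re(u), tolerance = 1e-10)
  ## zero residues kill both transform paths
  out0 <- ns$axisTransformF(v, rho, nu, array(0i, c(1, 1, 1)), modes = 3L)
  expect_equal(max(abs(out0$y)), 0)
})

test_that("LNO honors the batched tensor contract", {
  m <- buildLNO(2, layers = 2, width = 6, modes = 4, seed = 1)
  xb <- array(runif(20 * 41 * 41 * 2), c(41, 41, 2, 20))
  out <- ns$modelForward(m, xb, FALSE)
  expect_equal(dim(out$y), c(41, 41, 2, 20))
  expect_true(all(is.finite(out$y)))
})

test_that("training is deterministic, converges, and predicts consistently", {
  se <- tinyDatasetFixture()
  tr <- operatorData(se, 2, "grayscale", "train")
  cfg <- trainConfig("unet", "reduced", seed = 5L, n_updates = 60L,
                     batch_size = 4L, log_every = 10L)
  m <- buildOperator("unet", 2, "grayscale", "reduced", seed = 5L)
  f1 <- trainOperator(m, tr, cfg)
  f2 <- trainOperator(m, tr, cfg)
  expect_identical(f1@params, f2@params)
  expect_true(f1@trained)
  ## training loss decreases from the first to the last logged point
  expect_lt(tail(f1@history$loss, 1), f1@history$loss[1])
  ## batched and single-record prediction agree
  te <- operatorData(se, 2, "grayscale", "test")
  pb <- predictInsults(f1, te$x)
  p1 <- predictInsults(f1, te$x[, , , 1, drop = FALSE])
  expect_equal(pb[, , , 1], p1[, , , 1], tolerance = 1e-6)
  ## prediction is deterministic in eval mode
  expect_identical(pb, predictInsults(f1, te$x))
  ## encoding mismatch is rejected
  th <- operatorData(se, 2, "heat", "train")
  expect_error(trainOperator(m, th, cfg), "encoding")
})

test_that("every architecture can overfit a 5-record subset", {
  ## capacity sanity oracle: training relative L2 < 0.05 on 5 records
  se <- tinyDatasetFixture()
  d <- operatorData(se, 2, "grayscale", "train")
  sub <- list(x = d$x[, , , 1:5, drop = FALSE], y = d$y[, , , 1:5, drop = FALSE],
              profile = d$profile[, , 1:5, drop = FALSE], ids = d$ids[1:5],
              w = d$w[1:5], channels = 2L, encoding = "grayscale")
  budgets <- list(
    unet = list(n_updates = 900L),
    cnn_deeponet = list(n_updates = 2200L, lr = 5e-3, loss = "relative_l2",
                        schedule = "constant"),
    fnn_deeponet = list(n_updates = 2200L, lr = 6e-3, loss = "relative_l2",
                        schedule = "constant"),
    lno = list(n_updates = 300L))
  for (arch in names(budgets)) {
    cfg <- do.call(trainConfig,
                   c(list(arch = arch, tier = "reduced", seed = 2L,
                          batch_size = 5L, val_fraction = 0,
                          log_every = 50L), budgets[[arch]]))
    m <- buildOperator(arch, 2, "grayscale", "reduced", seed = 2L)
    m <- trainOperator(m, sub, cfg)
    pred <- predictInsults(m, sub$x)
    err <- vapply(1:5, function(r)
      relativeL2(pred[, , , r], sub$y[, , , r]), numeric(1))
    expect_lt(mean(err), 0.05, label = paste(arch, "training error"))
  }
})

test_that("the micro-scale study harness emits the full condition table", {
  se <- tinyDatasetFixture()
  res <- suppressMessages(reproduceStudy(
    se = se, tier = "reduced", seed = 1L, verbose = FALSE,
    config_overrides = list(
      unet = list(n_updates = 30L, batch_size = 4L),
      cnn_deeponet = list(n_updates = 30L, batch_size = 4L),
      fnn_deeponet = list(n_updates = 30L, batch_size = 4L),
      lno = list(n_updates = 30L, batch_size = 4L))))
  tab <- res$comparison$table
  expect_equal(nrow(tab), 16L)   # 4 architectures x 2 channels x 2 encodings
  expect_true(all(c("e_ce_filt", "e_delta_filt") %in% colnames(tab)))
  expect_equal(nrow(res$comparison$ratios), 8L)
  expect_true(all(res$comparison$table$e_ce >= 0))
  out <- file.path(tempdir(), "study_out")
  res2 <- suppressMessages(reproduceStudy(
    se = se, tier = "reduced", seed = 1L, verbose = FALSE, out_dir = out,
    archs = "fnn_deeponet", encodings = "heat",
    config_overrides = list(fnn_deeponet = list(n_updates = 20L,
                                                batch_size = 4L))))
  expect_true(file.exists(file.path(out, "condition_table.csv")))
})
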