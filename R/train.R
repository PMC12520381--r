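## Training loop (Adam + schedules) shared by all four architectures.

modelForward <- function(model, x, keep_cache = TRUE, ws = NULL) {
  switch(model@arch,
    unet = unetForward(model@params, x, model@spec, keep_cache, ws),
    cnn_deeponet = ,
    fnn_deeponet = deeponetForward(model@params, x, model@spec, keep_cache,
                                   ws = ws),
    lno = lnoForward(model@params, x, model@spec, keep_cache),
    stop("unknown architecture ", model@arch))
}

modelBackward <- function(model, cache, dy) {
  switch(model@arch,
    unet = unetBackward(model@params, cache, dy, model@spec),
    cnn_deeponet = ,
    fnn_deeponet = deeponetBackward(model@params, cache, dy, model@spec),
    lno = lnoBackward(model@params, cache, dy, model@spec))
}

#' Construct a training configuration
#'
#' Architecture-aware defaults at two budget tiers. The `"full"` tier
#' mirrors the published training budgets (200,000 weight updates for the
#' DeepONets and UNet, 225,000 for the LNO; constant learning rate 1e-3 for
#' the DeepONets, cosine-annealed 1e-4 for the UNet, exponentially decayed
#' 1e-3 for the LNO; mean-squared-error loss for the DeepONets, relative L2
#' for UNet and LNO). The `"reduced"` tier keeps the same structure at a
#' desk-scale budget of a few thousand updates and is what the bundled study
#' harness and acceptance checks run.
#'
#' @param arch One of `"unet"`, `"cnn_deeponet"`, `"fnn_deeponet"`, `"lno"`.
#' @param tier `"reduced"` or `"full"`.
#' @param seed Integer seed.
#' @param ... Overrides for any \linkS4class{TrainConfig} slot.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(arch = "unet", tier = c("reduced", "full"),
                        seed = 1L, ...) {
  tier <- match.arg(tier)
  base <- switch(arch,
    unet = list(lr = if (tier == "full") 1e-4 else 2e-3, schedule = "cosine",
                batch_size = if (tier == "full") 250L else 10L,
                n_updates = if (tier == "full") 200000L else 2000L,
                loss = "relative_l2", val_fraction = 0),
    cnn_deeponet = list(lr = 1e-3, schedule = "constant",
                        batch_size = if (tier == "full") 64L else 16L,
                        n_updates = if (tier == "full") 200000L else 2000L,
                        loss = "mse", val_fraction = 0),
    fnn_deeponet = list(lr = 1e-3, schedule = "constant",
                        batch_size = if (tier == "full") 64L else 16L,
                        n_updates = if (tier == "full") 200000L else 2000L,
                        loss = "mse", val_fraction = 0),
    lno = list(lr = if (tier == "full") 1e-3 else 2e-3,
               schedule = "exponential",
               batch_size = 20L,
               n_updates = if (tier == "full") 225000L else 1500L,
               loss = "relative_l2", val_fraction = 0.1),
    stop("unknown architecture ", arch))
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  new("TrainConfig", optimizer = "adam", lr = base$lr,
      schedule = base$schedule, batch_size = as.integer(base$batch_size),
      n_updates = as.integer(base$n_updates), loss = base$loss,
      normalization = base$normalization %||% "minmax",
      seed = as.integer(seed), tier = tier,
      val_fraction = base$val_fraction,
      log_every = as.integer(base$log_every %||% 50L))
}

#' Build an operator of a given architecture at a budget tier
#'
#' The `"full"` tier uses the default (publication-scale) widths; the
#' `"reduced"` tier uses slimmer widths suited to a few thousand weight
#' updates on one CPU while keeping each architecture's structure intact.
#'
#' @param arch Architecture tag.
#' @param channels 1 or 2 input channels.
#' @param encoding `"grayscale"` or `"heat"`.
#' @param tier `"reduced"` or `"full"`.
#' @param seed Initialization seed.
#' @return A \linkS4class{NeuralOperator}.
#' @export
buildOperator <- function(arch, channels = 2L, encoding = "grayscale",
                          tier = c("reduced", "full"), seed = 1L) {
  tier <- match.arg(tier)
  if (tier == "full") {
    switch(arch,
      unet = buildUNet(channels, encoding = encoding, seed = seed),
      cnn_deeponet = buildCNNDeepONet(channels, encoding = encoding, seed = seed),
      fnn_deeponet = buildFNNDeepONet(channels, encoding = encoding, seed = seed),
      lno = buildLNO(channels, encoding = encoding, seed = seed),
      stop("unknown architecture ", arch))
  } else {
    switch(arch,
      unet = buildUNet(channels, width = 10L, groups = 2L, blocks = "single",
                       encoding = encoding, seed = seed),
      cnn_deeponet = buildCNNDeepONet(channels, conv_channels = c(8L, 16L, 32L),
                                      dense_hidden = 128L, p = 64L,
                                      trunk_width = 64L, encoding = encoding,
                                      seed = seed),
      fnn_deeponet = buildFNNDeepONet(channels, hidden = c(64L, 64L), p = 64L,
                                      trunk_width = 64L, encoding = encoding,
                                      seed = seed),
      lno = buildLNO(channels, layers = 4L, width = 16L, modes = 6L,
                     encoding = encoding, seed = seed),
      stop("unknown architecture ", arch))
  }
}

normStats <- function(a, dim_c = 3L) {
  nc <- dim(a)[dim_c]
  lo <- hi <- numeric(nc)
  for (c_ in seq_len(nc)) {
    v <- a[, , c_, , drop = FALSE]
    lo[c_] <- min(v); hi[c_] <- max(v)
  }
  hi <- pmax(hi, lo + 1e-8)
  list(lo = lo, hi = hi)
}

applyNorm <- function(a, st) {
  for (c_ in seq_len(dim(a)[3]))
    a[, , c_, ] <- (a[, , c_, ] - st$lo[c_]) / (st$hi[c_] - st$lo[c_])
  a
}

invertNorm <- function(a, st) {
  for (c_ in seq_len(dim(a)[3]))
    a[, , c_, ] <- a[, , c_, ] * (st$hi[c_] - st$lo[c_]) + st$lo[c_]
  a
}

#' @describeIn trainOperator Adam training with the configured schedule and
#'   loss; deterministic given the config seed. If `val_fraction > 0` a
#'   carve-out of the training records is scored periodically and the
#'   best-scoring parameters are returned (best-model selection, used by the
#'   LNO); otherwise the final parameters are returned.
setMethod("trainOperator", signature(model = "NeuralOperator", data = "list",
                                     config = "TrainConfig"),
  function(model, data, config) {
    stopifnot(dim(data$x)[3] == model@channels)
    if (!is.null(data$encoding) && data$encoding != model@encoding)
      stop("dataset encoding '", data$encoding,
           "' does not match the model's expected encoding '",
           model@encoding, "'")
    x <- data$x; y <- data$y
    n <- dim(x)[4]
    if (config@normalization == "minmax") {
      nx <- normStats(x); ny <- normStats(y)
    } else {
      nx <- list(lo = rep(0, dim(x)[3]), hi = rep(1, dim(x)[3]))
      ny <- list(lo = rep(0, dim(y)[3]), hi = rep(1, dim(y)[3]))
    }
    model@norm <- list(x = nx, y = ny)
    x <- applyNorm(x, nx); y <- applyNorm(y, ny)
    val_idx <- integer(0)
    tr_idx <- seq_len(n)
    hist_up <- hist_loss <- hist_val <- numeric(0)
    best <- list(score = Inf, params = NULL)
    withSeed(config@seed, {
      if (config@val_fraction > 0) {
        n_val <- max(1L, round(config@val_fraction * n))
        val_idx <- sample(n, n_val)
        tr_idx <- setdiff(seq_len(n), val_idx)
      }
      state <- adamInit(model@params)
      params <- model@params
      ws <- new.env(parent = emptyenv())
      for (t in seq_len(config@n_updates)) {
        lr <- lrAt(config@schedule, config@lr, t, config@n_updates)
        bi <- if (length(tr_idx) >= config@batch_size)
          sample(tr_idx, config@batch_size) else
          sample(tr_idx, config@batch_size, replace = TRUE)
        xb <- x[, , , bi, drop = FALSE]
        yb <- y[, , , bi, drop = FALSE]
        model@params <- params
        fw <- modelForward(model, xb, keep_cache = TRUE, ws = ws)
        lg <- lossGrad(fw$y, yb, config@loss)
        if (!is.finite(lg$loss))
          stop("training error: non-finite loss at update ", t,
               " (last logged losses: ",
               paste(signif(utils::tail(hist_loss, 5), 4), collapse = ", "), ")")
        grads <- modelBackward(model, fw$cache, lg$grad)
        st <- adamStep(params, grads, state, lr)
        params <- st$params; state <- st$state
        if (t %% config@log_every == 0L || t == 1L || t == config@n_updates) {
          vl <- NA_real_
          if (length(val_idx)) {
            model@params <- params
            pv <- modelForward(model, x[, , , val_idx, drop = FALSE],
                               keep_cache = FALSE)
            vl <- lossGrad(pv$y, y[, , , val_idx, drop = FALSE],
                           "relative_l2")$loss
            if (vl < best$score) best <- list(score = vl, params = params)
          }
          hist_up <- c(hist_up, t)
          hist_loss <- c(hist_loss, lg$loss)
          hist_val <- c(hist_val, vl)
        }
      }
      model@params <- if (!is.null(best$params)) best$params else params
    })
    model@trained <- TRUE
    model@history <- data.frame(update = hist_up, loss = hist_loss,
                                val = hist_val)
    model
  })

#' @describeIn predictInsults Forward evaluation in eval mode; inputs are
#'   normalized with the constants fitted at training time and predictions
#'   are returned de-normalized, in physical insult units.
setMethod("predictInsults", signature(model = "NeuralOperator"),
  function(model, x) {
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L, 1L)
    if (dim(x)[3] != model@channels)
      stop("input error: model expects ", model@channels, " channel(s), got ",
           dim(x)[3])
    if (length(model@norm)) x <- applyNorm(x, model@norm$x)
    y <- modelForward(model, x, keep_cache = FALSE)$y
    if (length(model@norm)) y <- invertNorm(y, model@norm$y)
    y
  })
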