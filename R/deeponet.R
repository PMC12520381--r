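## Deep operator networks: a branch network embeds the input maps, a trunk
## network embeds the normalized output coordinates {theta_hat, z_hat}, and
## each insult head is the element-wise dot product of its half of the two
## embeddings (plus a scalar bias). Both heads share one parameter set by
## splitting the embedding; activations are SiLU.

## trunk input: cylindrical coordinates as a harmonic positional encoding.
## theta enters through its first `n_harm` circular harmonics (respecting
## the periodic wrap); z through z_hat plus sine/cosine harmonics on [0, 1].
## The encoding makes the trunk basis expressive enough to form localized
## lesion shapes within desk-scale training budgets.
deeponetCoords <- function(grid = gridSpec(), n_harm = 4L) {
  co <- gridCoords(grid)
  th <- as.vector(matrix(co$theta, grid@n_theta, grid@n_z))
  zh <- as.vector(matrix(co$z_hat, grid@n_theta, grid@n_z, byrow = TRUE))
  k <- seq_len(n_harm)
  cbind(cos(outer(th, k)), sin(outer(th, k)),
        zh, cos(outer(pi * zh, k)), sin(outer(pi * zh, k)))
}

#' Build a DeepONet operator with a convolutional branch
#'
#' @param channels 1 or 2 input map channels; with 1 channel the branch path
#'   encoding distensibility is simply absent.
#' @param conv_channels Channel widths of the three convolution stages.
#' @param dense_hidden Width of the dense layer after flattening.
#' @param p Embedding dimension (even; split across the two heads).
#' @param trunk_width Trunk hidden width.
#' @param encoding Input encoding the model will be trained on.
#' @param seed Seed for initialization.
#' @return A \linkS4class{DeepONetOperator}.
#' @export
buildCNNDeepONet <- function(channels = 2L, conv_channels = c(16L, 32L, 64L),
                             dense_hidden = 768L, p = 128L, trunk_width = 128L,
                             encoding = "grayscale", seed = 1L) {
  channels <- as.integer(channels)
  stopifnot(channels %in% c(1L, 2L), p %% 2L == 0L)
  cc <- as.integer(conv_channels)
  flat <- 6L * 6L * cc[3]
  params <- withSeed(seed, {
    p_ <- list(
      br_cv1_W = heInit(c(9 * channels, cc[1]), 9 * channels),
      br_cv1_b = numeric(cc[1]),
      br_cv2_W = heInit(c(9 * cc[1], cc[2]), 9 * cc[1]),
      br_cv2_b = numeric(cc[2]),
      br_cv3_W = heInit(c(9 * cc[2], cc[3]), 9 * cc[2]),
      br_cv3_b = numeric(cc[3]),
      br_d1_W = heInit(c(flat, dense_hidden), flat),
      br_d1_b = numeric(dense_hidden),
      br_d2_W = heInit(c(dense_hidden, p), dense_hidden, gain = 1),
      br_d2_b = numeric(p))
    c(p_, deeponetTrunkParams(trunk_width, p), list(head_b = numeric(2)))
  })
  new("DeepONetOperator", arch = "cnn_deeponet", branch = "convolutional",
      channels = channels, encoding = encoding,
      spec = list(branch = "cnn", conv_channels = cc,
                  dense_hidden = as.integer(dense_hidden), p = as.integer(p),
                  trunk_width = as.integer(trunk_width), n_grid = 41L,
                  pad_to = 48L, act = "silu", coords = deeponetCoords()),
      params = params)
}

#' Build a DeepONet operator with a feed-forward branch
#'
#' @inheritParams buildCNNDeepONet
#' @param hidden Widths of the two dense branch hidden layers.
#' @return A \linkS4class{DeepONetOperator}.
#' @export
buildFNNDeepONet <- function(channels = 2L, hidden = c(80L, 80L), p = 128L,
                             trunk_width = 80L, encoding = "heat", seed = 1L) {
  channels <- as.integer(channels)
  stopifnot(channels %in% c(1L, 2L), p %% 2L == 0L)
  nin <- 41L * 41L * channels
  params <- withSeed(seed, {
    p_ <- list(
      br_d1_W = heInit(c(nin, hidden[1]), nin), br_d1_b = numeric(hidden[1]),
      br_d2_W = heInit(c(hidden[1], hidden[2]), hidden[1]),
      br_d2_b = numeric(hidden[2]),
      br_d3_W = heInit(c(hidden[2], p), hidden[2], gain = 1),
      br_d3_b = numeric(p))
    c(p_, deeponetTrunkParams(trunk_width, p), list(head_b = numeric(2)))
  })
  new("DeepONetOperator", arch = "fnn_deeponet", branch = "feed-forward",
      channels = channels, encoding = encoding,
      spec = list(branch = "fnn", hidden = as.integer(hidden),
                  p = as.integer(p), trunk_width = as.integer(trunk_width),
                  n_grid = 41L, act = "silu", coords = deeponetCoords()),
      params = params)
}

deeponetTrunkParams <- function(tw, p, n_in = 17L) {
  list(tr_1_W = heInit(c(n_in, tw), n_in), tr_1_b = numeric(tw),
       tr_2_W = heInit(c(tw, tw), tw), tr_2_b = numeric(tw),
       tr_3_W = heInit(c(tw, p), tw, gain = 1), tr_3_b = numeric(p))
}

deeponetTrunkF <- function(params, coords, act) {
  t1 <- denseForward(coords, params$tr_1_W, params$tr_1_b)
  a1 <- actForward(t1$y, act)
  t2 <- denseForward(a1$y, params$tr_2_W, params$tr_2_b)
  a2 <- actForward(t2$y, act)
  t3 <- denseForward(a2$y, params$tr_3_W, params$tr_3_b)
  list(y = t3$y, t1 = t1, a1 = a1, t2 = t2, a2 = a2, t3 = t3)
}

deeponetTrunkB <- function(params, cache, dT, grads) {
  b3 <- denseBackward(cache$t3, params$tr_3_W, dT)
  grads$tr_3_W <- b3$dW; grads$tr_3_b <- b3$db
  da2 <- actBackward(cache$a2, b3$dx)
  b2 <- denseBackward(cache$t2, params$tr_2_W, da2)
  grads$tr_2_W <- b2$dW; grads$tr_2_b <- b2$db
  da1 <- actBackward(cache$a1, b2$dx)
  b1 <- denseBackward(cache$t1, params$tr_1_W, da1)
  grads$tr_1_W <- b1$dW; grads$tr_1_b <- b1$db
  grads
}

## matrix layout (HW*B x C) -> per-record feature rows (B x HW*C)
flattenBatch <- function(xm, HW, B) {
  C <- ncol(xm)
  dim(xm) <- c(HW, B, C)
  xm <- aperm(xm, c(2, 1, 3))
  dim(xm) <- c(B, HW * C)
  xm
}

unflattenBatch <- function(f, HW, B) {
  C <- ncol(f) %/% HW
  dim(f) <- c(B, HW, C)
  f <- aperm(f, c(2, 1, 3))
  dim(f) <- c(HW * B, C)
  f
}

deeponetBranchF <- function(params, x, spec, ws) {
  B <- dim(x)[4]
  n <- spec$n_grid
  if (spec$branch == "fnn") {
    f0 <- flattenBatch(arr4ToMat(x), n * n, B)
    d1 <- denseForward(f0, params$br_d1_W, params$br_d1_b)
    a1 <- actForward(d1$y, spec$act)
    d2 <- denseForward(a1$y, params$br_d2_W, params$br_d2_b)
    a2 <- actForward(d2$y, spec$act)
    d3 <- denseForward(a2$y, params$br_d3_W, params$br_d3_b)
    return(list(y = d3$y, type = "fnn", d1 = d1, a1 = a1, d2 = d2, a2 = a2,
                d3 = d3))
  }
  np <- spec$pad_to
  pd <- padReflectForward(arr4ToMat(x), n, np, B)
  c1 <- conv3Forward(pd$y, params$br_cv1_W, params$br_cv1_b, np, np, B, ws)
  a1 <- actForward(c1$y, spec$act)
  p1 <- maxPoolForward(a1$y, np, np, B)
  h2 <- np %/% 2L
  c2 <- conv3Forward(p1$y, params$br_cv2_W, params$br_cv2_b, h2, h2, B, ws)
  a2 <- actForward(c2$y, spec$act)
  p2 <- maxPoolForward(a2$y, h2, h2, B)
  h4 <- h2 %/% 2L
  c3 <- conv3Forward(p2$y, params$br_cv3_W, params$br_cv3_b, h4, h4, B, ws)
  a3 <- actForward(c3$y, spec$act)
  p3 <- maxPoolForward(a3$y, h4, h4, B)
  h8 <- h4 %/% 2L
  fl <- flattenBatch(p3$y, h8 * h8, B)
  d1 <- denseForward(fl, params$br_d1_W, params$br_d1_b)
  a4 <- actForward(d1$y, spec$act)
  d2 <- denseForward(a4$y, params$br_d2_W, params$br_d2_b)
  list(y = d2$y, type = "cnn", pd = pd, c1 = c1, a1 = a1, p1 = p1, c2 = c2,
       a2 = a2, p2 = p2, c3 = c3, a3 = a3, p3 = p3, B = B,
       dims = c(np, h2, h4, h8), d1 = d1, a4 = a4, d2 = d2)
}

deeponetBranchB <- function(params, cache, dE, grads, ws) {
  if (cache$type == "fnn") {
    b3 <- denseBackward(cache$d3, params$br_d3_W, dE)
    grads$br_d3_W <- b3$dW; grads$br_d3_b <- b3$db
    da2 <- actBackward(cache$a2, b3$dx)
    b2 <- denseBackward(cache$d2, params$br_d2_W, da2)
    grads$br_d2_W <- b2$dW; grads$br_d2_b <- b2$db
    da1 <- actBackward(cache$a1, b2$dx)
    b1 <- denseBackward(cache$d1, params$br_d1_W, da1)
    grads$br_d1_W <- b1$dW; grads$br_d1_b <- b1$db
    return(grads)
  }
  B <- cache$B
  np <- cache$dims[1]; h2 <- cache$dims[2]; h4 <- cache$dims[3]
  h8 <- cache$dims[4]
  b2 <- denseBackward(cache$d2, params$br_d2_W, dE)
  grads$br_d2_W <- b2$dW; grads$br_d2_b <- b2$db
  da4 <- actBackward(cache$a4, b2$dx)
  b1 <- denseBackward(cache$d1, params$br_d1_W, da4)
  grads$br_d1_W <- b1$dW; grads$br_d1_b <- b1$db
  dfl <- unflattenBatch(b1$dx, h8 * h8, B)
  dp3 <- maxPoolBackward(cache$p3, dfl)
  da3 <- actBackward(cache$a3, dp3)
  cb3 <- conv3Backward(cache$c3, params$br_cv3_W, da3, h4, h4, B, ws)
  grads$br_cv3_W <- cb3$dW; grads$br_cv3_b <- cb3$db
  dp2 <- maxPoolBackward(cache$p2, cb3$dx)
  da2 <- actBackward(cache$a2, dp2)
  cb2 <- conv3Backward(cache$c2, params$br_cv2_W, da2, h2, h2, B, ws)
  grads$br_cv2_W <- cb2$dW; grads$br_cv2_b <- cb2$db
  dp1 <- maxPoolBackward(cache$p1, cb2$dx)
  da1 <- actBackward(cache$a1, dp1)
  cb1 <- conv3Backward(cache$c1, params$br_cv1_W, da1, np, np, B, ws)
  grads$br_cv1_W <- cb1$dW; grads$br_cv1_b <- cb1$db
  grads
}

deeponetForward <- function(params, x, spec, keep_cache = TRUE,
                            coords = NULL, ws = NULL) {
  if (is.null(ws)) ws <- new.env(parent = emptyenv())
  br <- deeponetBranchF(params, x, spec, ws)
  if (is.null(coords)) coords <- spec$coords
  tr <- deeponetTrunkF(params, coords, spec$act)
  p <- spec$p
  h <- p %/% 2L
  B1 <- br$y[, seq_len(h), drop = FALSE]
  B2 <- br$y[, h + seq_len(h), drop = FALSE]
  T1 <- tr$y[, seq_len(h), drop = FALSE]
  T2 <- tr$y[, h + seq_len(h), drop = FALSE]
  Y1 <- tcrossprod(B1, T1) + params$head_b[1]
  Y2 <- tcrossprod(B2, T2) + params$head_b[2]
  n <- spec$n_grid
  B <- nrow(Y1)
  y <- array(0, c(n, n, 2L, B))
  y[, , 1L, ] <- array(t(Y1), c(n, n, B))
  y[, , 2L, ] <- array(t(Y2), c(n, n, B))
  out <- list(y = y)
  if (keep_cache) out$cache <- list(br = br, tr = tr, h = h, ws = ws,
                                    B1 = B1, B2 = B2, T1 = T1, T2 = T2)
  out
}

deeponetBackward <- function(params, cache, dy, spec) {
  n <- spec$n_grid
  B <- dim(dy)[4]
  dY1 <- t(matrix(dy[, , 1L, ], n * n, B))
  dY2 <- t(matrix(dy[, , 2L, ], n * n, B))
  grads <- list(head_b = c(sum(dY1), sum(dY2)))
  dE <- cbind(dY1 %*% cache$T1, dY2 %*% cache$T2)
  dT <- cbind(crossprod(dY1, cache$B1), crossprod(dY2, cache$B2))
  grads <- deeponetTrunkB(params, cache$tr, dT, grads)
  deeponetBranchB(params, cache$br, dE, grads, cache$ws)
}
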