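## Self-contained reverse-mode neural network core. Activations live in a
## flat matrix layout (H*W*B) x C with row order i + H*j + H*W*b, so batch
## blocks are contiguous and every layer reduces to dgemm plus cheap row
## indexing; spatial sizes (H, W, B) travel alongside explicitly. The 3x3
## convolution lowers to one dgemm through the compiled im2col/col2im
## kernels. Every layer exposes an explicit forward (output + cache) and
## backward (input gradient + parameter gradients); gradients are verified
## against finite differences in the test suite.

#' @useDynLib TAAinvert, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---- boundary conversions between array (H,W,C,B) and matrix layout ----

arr4ToMat <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1] * d[2], d[3], d[4])
  a <- aperm(a, c(1, 3, 2))
  dim(a) <- c(d[1] * d[2] * d[4], d[3])
  a
}

matToArr4 <- function(m, H, W, B) {
  C <- ncol(m)
  dim(m) <- c(H * W, B, C)
  m <- aperm(m, c(1, 3, 2))
  dim(m) <- c(H, W, C, B)
  m
}

## ---- initialization ----

heInit <- function(dims, fan_in, gain = 2) {
  array(rnorm(prod(dims), sd = sqrt(gain / fan_in)), dims)
}

addBias <- function(y, b) y + rep(b, each = nrow(y))

## ---- 3x3 convolution (zero pad, stride 1) ----
## The large im2col scratch lives in a per-training-run workspace
## environment and is reused across updates (keyed by shape), keeping the
## allocation rate - and hence R's GC - out of the hot loop. Backward
## recomputes im2col into the same scratch instead of caching it.

wsBuffer <- function(ws, key, nrow, ncol) {
  buf <- ws[[key]]
  if (is.null(buf) || nrow(buf) != nrow || ncol(buf) != ncol) {
    buf <- matrix(0, nrow, ncol)
    ws[[key]] <- buf
  }
  buf
}

conv3Forward <- function(x, W, b, H, Wd, B, ws) {
  K <- wsBuffer(ws, sprintf("K_%d_%d_%d", H * Wd * B, nrow(W), 1L),
                H * Wd * B, nrow(W))
  im2col3_into(x, H, Wd, B, K)
  y <- K %*% W
  if (!is.null(b)) y <- addBias(y, b)
  list(y = y, x = x)
}

conv3Backward <- function(cache, W, dy, H, Wd, B, ws, bias = TRUE) {
  Ci <- nrow(W) %/% 9L
  K <- wsBuffer(ws, sprintf("K_%d_%d_%d", H * Wd * B, nrow(W), 1L),
                H * Wd * B, nrow(W))
  im2col3_into(cache$x, H, Wd, B, K)
  dW <- crossprod(K, dy)
  dgemm_nt_into(dy, W, K)          # K now holds dy %*% t(W)
  dx <- col2im3(K, H, Wd, B, Ci)
  out <- list(dx = dx, dW = dW)
  if (bias) out$db <- colSums(dy)
  out
}

## ---- 1x1 convolution / channel mixing ----

conv1Forward <- function(x, W, b) list(y = addBias(x %*% W, b), x = x)

conv1Backward <- function(cache, W, dy) {
  list(dx = tcrossprod(dy, W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

## ---- spatial row-index helpers ----

## memoized spatial index vectors (shapes recur every update)
.idxCache <- new.env(parent = emptyenv())

memoIdx <- function(key, builder) {
  v <- .idxCache[[key]]
  if (is.null(v)) {
    v <- builder()
    .idxCache[[key]] <- v
  }
  v
}

## row indices of the four 2x2-pool phases; output rows ordered for the
## (H/2, W/2, B) grid
poolIdx <- function(H, W, B) {
  i2 <- seq(1, H, 2); j2 <- seq(1, W, 2)
  base <- outer(i2, (j2 - 1) * H, "+")                  # (H/2) x (W/2)
  base <- as.vector(base)
  off <- rep((seq_len(B) - 1) * H * W, each = length(base))
  base <- rep(base, B) + off
  list(p1 = base, p2 = base + 1L, p3 = base + H, p4 = base + H + 1L)
}

maxPoolForward <- function(x, H, W, B) {
  r <- maxpool_fw(x, H, W, B)
  r$H <- H; r$W <- W; r$B <- B
  r
}

maxPoolBackward <- function(cache, dy) {
  maxpool_bw(dy, cache$mask, cache$H, cache$W, cache$B)
}

## ---- 2x2 stride-2 transpose convolution (upsampling) ----

convT2Forward <- function(x, W, b, H, Wd, B) {
  Ci <- dim(W)[3]; Co <- dim(W)[4]
  idx <- memoIdx(sprintf("pool_%d_%d_%d", 2 * H, 2 * Wd, B),
                 function() poolIdx(2 * H, 2 * Wd, B))
  y <- matrix(0, 4 * H * Wd * B, Co)
  ph <- list(idx$p1, idx$p2, idx$p3, idx$p4)  # (dy,dx) = (1,1),(2,1),(1,2),(2,2)
  key <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (k in 1:4) {
    Ws <- matrix(W[key[[k]][1], key[[k]][2], , ], Ci, Co)
    y[ph[[k]], ] <- x %*% Ws
  }
  list(y = addBias(y, b), x = x, idx = idx, key = key)
}

convT2Backward <- function(cache, W, dy) {
  Ci <- dim(W)[3]; Co <- dim(W)[4]
  dW <- array(0, dim(W))
  dx <- matrix(0, nrow(cache$x), Ci)
  db <- numeric(Co)
  ph <- list(cache$idx$p1, cache$idx$p2, cache$idx$p3, cache$idx$p4)
  for (k in 1:4) {
    dyk <- dy[ph[[k]], , drop = FALSE]
    Ws <- matrix(W[cache$key[[k]][1], cache$key[[k]][2], , ], Ci, Co)
    dW[cache$key[[k]][1], cache$key[[k]][2], , ] <- crossprod(cache$x, dyk)
    dx <- dx + tcrossprod(dyk, Ws)
    db <- db + colSums(dyk)
  }
  list(dx = dx, dW = dW, db = db)
}

## ---- group normalization ----
## statistics per (batch, group) over the H*W*Cg entries; batch blocks are
## contiguous rows so the reductions are zero-copy dim tricks

groupNormForward <- function(x, gamma, beta, G, HW, B, eps = 1e-5) {
  r <- groupnorm_fw(x, gamma, beta, G, HW, B, eps)
  r$G <- G; r$HW <- HW; r$B <- B
  r
}

groupNormBackward <- function(cache, dy, gamma) {
  groupnorm_bw(dy, cache$xhat, cache$isd, gamma, cache$G, cache$HW, cache$B)
}

## ---- activations ----

.GELU_A <- sqrt(2 / pi)

actForward <- function(x, type) {
  switch(type,
    gelu = {
      r <- gelu_fw(x)
      list(y = r$y, x = x, th = r$th, type = type)
    },
    silu = {
      s <- 1 / (1 + exp(-x))
      list(y = x * s, x = x, s = s, type = type)
    },
    sine = list(y = sin(x), x = x, type = type),
    identity = list(y = x, type = type))
}

actBackward <- function(cache, dy) {
  switch(cache$type,
    gelu = gelu_bw(cache$x, cache$th, dy),
    silu = {
      s <- cache$s
      dy * (s * (1 + cache$x * (1 - s)))
    },
    sine = dy * cos(cache$x),
    identity = dy)
}

## ---- dense ----

denseForward <- function(x, W, b) list(y = addBias(x %*% W, b), x = x)

denseBackward <- function(cache, W, dy) {
  list(dx = tcrossprod(dy, W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

## ---- reflect padding (n_from -> n_to rows/cols) ----

reflectIdx <- function(n_from, n_to) {
  pad <- n_to - n_from
  pl <- pad %/% 2
  pr <- pad - pl
  c((pl + 1L):2L, seq_len(n_from), (n_from - 1L):(n_from - pr))
}

## row map from the (n_to, n_to, B) padded grid to the (n, n, B) source grid
padRowMap <- function(n, n_to, B) {
  idx <- reflectIdx(n, n_to)
  base <- outer(idx, (idx - 1L) * n, "+")        # n_to x n_to source rows
  base <- as.vector(base)
  rep(base, B) + rep((seq_len(B) - 1L) * n * n, each = length(base))
}

padReflectForward <- function(x, n, n_to, B, rowmap = NULL) {
  if (is.null(rowmap))
    rowmap <- memoIdx(sprintf("pad_%d_%d_%d", n, n_to, B),
                      function() padRowMap(n, n_to, B))
  list(y = x[rowmap, , drop = FALSE], rowmap = rowmap, n_in = n * n * B)
}

padReflectBackward <- function(cache, dy) {
  dx <- rowsum(dy, cache$rowmap)     # groups sorted = rows 1..n_in, all hit
  dimnames(dx) <- NULL
  dx
}

## keep the central n_out x n_out window of an (n_in, n_in, B) grid
cropRowKeep <- function(n_in, n_out, B) {
  pl <- (n_in - n_out) %/% 2
  idx <- (pl + 1L):(pl + n_out)
  base <- as.vector(outer(idx, (idx - 1L) * n_in, "+"))
  rep(base, B) + rep((seq_len(B) - 1L) * n_in * n_in, each = length(base))
}

cropForward <- function(x, n_in, n_out, B, keep = NULL) {
  if (is.null(keep))
    keep <- memoIdx(sprintf("crop_%d_%d_%d", n_in, n_out, B),
                    function() cropRowKeep(n_in, n_out, B))
  list(y = x[keep, , drop = FALSE], keep = keep, n_in_rows = n_in * n_in * B)
}

cropBackward <- function(cache, dy) {
  dx <- matrix(0, cache$n_in_rows, ncol(dy))
  dx[cache$keep, ] <- dy
  dx
}

## ---- optimizer ----

`%||%` <- function(a, b) if (is.null(a)) b else a

adamInit <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## learning-rate schedules over the update budget
lrAt <- function(schedule, lr0, t, t_total) {
  switch(schedule,
    constant = lr0,
    cosine = lr0 / 2 * (1 + cos(pi * t / t_total)),
    exponential = lr0 * 0.1^(t / t_total))
}

## ---- losses (on normalized (41,41,2,B) arrays) ----
## relative_l2: mean over records of the joint (both-channel) Frobenius
## relative error; mse: plain mean squared error

lossGrad <- function(pred, truth, type, eps = 1e-8) {
  d <- dim(pred)
  B <- d[4]
  diff <- pred - truth
  if (type == "mse") {
    n <- length(pred)
    return(list(loss = sum(diff * diff) / n, grad = 2 * diff / n))
  }
  dm <- matrix(diff, ncol = B)
  tm <- matrix(truth, ncol = B)
  num <- sqrt(colSums(dm * dm))
  den <- pmax(sqrt(colSums(tm * tm)), eps)
  loss <- mean(num / den)
  gm <- sweep(dm, 2, B * den * pmax(num, eps), "/")
  list(loss = loss, grad = array(gm, d))
}
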