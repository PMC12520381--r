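## UNet: encoder-decoder with skip connections on the 41x41 maps,
## reflect-padded to 48x48 so the two 2x2 max-pool stages divide evenly, and
## cropped back on output. Each stage is Conv2D -> GroupNorm -> GELU; 2x2
## max-pooling downsamples and 2x2 stride-2 transpose convolutions upsample.
## Convolution weights are stored gemm-ready as (9*Cin) x Cout.

#' Build a UNet operator
#'
#' Two variants share the U-shape (reflect pad 41 to 48, two max-pool
#' levels, transpose-convolution upsampling, skip connections,
#' Conv2D/GroupNorm/GELU stages): `blocks = "double"` uses two convolution
#' stages per level (the publication-scale default, about 1.9M parameters at
#' `width = 64`); `blocks = "single"` uses one stage per level, suited to
#' desk-scale training budgets.
#'
#' @param channels 1 (dilatation only) or 2 (dilatation + distensibility).
#' @param width Base channel width; doubles at each encoder level.
#' @param groups Group-normalization groups (must divide `width`).
#' @param blocks `"double"` or `"single"` convolution stages per level.
#' @param encoding Input encoding the model will be trained on.
#' @param seed Seed for parameter initialization.
#' @return A \linkS4class{UNetOperator}.
#' @export
buildUNet <- function(channels = 2L, width = 64L, groups = 4L,
                      blocks = c("double", "single"),
                      encoding = "grayscale", seed = 1L) {
  channels <- as.integer(channels)
  blocks <- match.arg(blocks)
  stopifnot(channels %in% c(1L, 2L), width %% groups == 0L)
  w <- as.integer(width)
  conv <- function(ci, co) list(W = heInit(c(9 * ci, co), 9 * ci))
  gn <- function(co) list(g = rep(1, co), be = numeric(co))
  convT <- function(ci, co) list(W = heInit(c(2, 2, ci, co), ci),
                                 b = numeric(co))
  stages <- if (blocks == "double")
    list(e1a = c(channels, w), e1b = c(w, w),
         e2a = c(w, 2 * w), e2b = c(2 * w, 2 * w),
         ba = c(2 * w, 4 * w), bb = c(4 * w, 4 * w),
         d1a = c(4 * w, 2 * w), d1b = c(2 * w, 2 * w),
         d2a = c(2 * w, w), d2b = c(w, w))
  else
    list(e1a = c(channels, w), e2a = c(w, 2 * w), ba = c(2 * w, 4 * w),
         d1a = c(4 * w, 2 * w), d2a = c(2 * w, w))
  params <- withSeed(seed, {
    p <- list()
    add <- function(p, nm, l) { for (k in names(l)) p[[paste0(nm, "_", k)]] <- l[[k]]; p }
    for (nm in names(stages)) {
      p <- add(p, nm, conv(stages[[nm]][1], stages[[nm]][2]))
      p <- add(p, nm, gn(stages[[nm]][2]))
    }
    p <- add(p, "u1", convT(4 * w, 2 * w))
    p <- add(p, "u2", convT(2 * w, w))
    p[["head_W"]] <- heInit(c(w, 2), w, gain = 1)
    p[["head_b"]] <- numeric(2)
    p
  })
  new("UNetOperator", arch = "unet", channels = channels, encoding = encoding,
      spec = list(width = w, groups = as.integer(groups), pad_to = 48L,
                  n_grid = 41L, act = "gelu", blocks = blocks),
      params = params)
}

## conv3 (no bias; the following group norm absorbs it) -> group norm -> act
unetBlockF <- function(x, p, nm, G, act, H, W, B, ws) {
  cv <- conv3Forward(x, p[[paste0(nm, "_W")]], NULL, H, W, B, ws)
  gn <- groupNormForward(cv$y, p[[paste0(nm, "_g")]], p[[paste0(nm, "_be")]],
                         G, H * W, B)
  ac <- actForward(gn$y, act)
  list(y = ac$y, cv = cv, gn = gn, ac = ac, H = H, W = W, B = B)
}

unetBlockB <- function(cache, p, nm, dy, grads, ws) {
  da <- actBackward(cache$ac, dy)
  gb <- groupNormBackward(cache$gn, da, p[[paste0(nm, "_g")]])
  cb <- conv3Backward(cache$cv, p[[paste0(nm, "_W")]], gb$dx,
                      cache$H, cache$W, cache$B, ws, bias = FALSE)
  grads[[paste0(nm, "_W")]] <- cb$dW
  grads[[paste0(nm, "_g")]] <- gb$dgamma
  grads[[paste0(nm, "_be")]] <- gb$dbeta
  list(dx = cb$dx, grads = grads)
}

unetForward <- function(params, x, spec, keep_cache = TRUE, ws = NULL) {
  if (is.null(ws)) ws <- new.env(parent = emptyenv())
  G <- spec$groups
  B <- dim(x)[4]
  n <- spec$n_grid
  np <- spec$pad_to
  h2 <- np %/% 2L
  h4 <- h2 %/% 2L
  dbl <- spec$blocks == "double"
  cc <- list(B = B)
  pd <- padReflectForward(arr4ToMat(x), n, np, B)
  v <- unetBlockF(pd$y, params, "e1a", G, spec$act, np, np, B, ws)
  cc$e1a <- v
  if (dbl) { v <- unetBlockF(v$y, params, "e1b", G, spec$act, np, np, B, ws); cc$e1b <- v }
  skip1 <- v$y
  p1 <- maxPoolForward(skip1, np, np, B)
  v <- unetBlockF(p1$y, params, "e2a", G, spec$act, h2, h2, B, ws)
  cc$e2a <- v
  if (dbl) { v <- unetBlockF(v$y, params, "e2b", G, spec$act, h2, h2, B, ws); cc$e2b <- v }
  skip2 <- v$y
  p2 <- maxPoolForward(skip2, h2, h2, B)
  v <- unetBlockF(p2$y, params, "ba", G, spec$act, h4, h4, B, ws)
  cc$ba <- v
  if (dbl) { v <- unetBlockF(v$y, params, "bb", G, spec$act, h4, h4, B, ws); cc$bb <- v }
  u1 <- convT2Forward(v$y, params$u1_W, params$u1_b, h4, h4, B)
  v <- unetBlockF(cbind(u1$y, skip2), params, "d1a", G, spec$act, h2, h2, B, ws)
  cc$d1a <- v
  if (dbl) { v <- unetBlockF(v$y, params, "d1b", G, spec$act, h2, h2, B, ws); cc$d1b <- v }
  u2 <- convT2Forward(v$y, params$u2_W, params$u2_b, h2, h2, B)
  v <- unetBlockF(cbind(u2$y, skip1), params, "d2a", G, spec$act, np, np, B, ws)
  cc$d2a <- v
  if (dbl) { v <- unetBlockF(v$y, params, "d2b", G, spec$act, np, np, B, ws); cc$d2b <- v }
  hd <- conv1Forward(v$y, params$head_W, params$head_b)
  cr <- cropForward(hd$y, np, n, B)
  out <- list(y = matToArr4(cr$y, n, n, B))
  if (keep_cache) {
    cc$pd <- pd; cc$p1 <- p1; cc$p2 <- p2; cc$u1 <- u1; cc$u2 <- u2
    cc$hd <- hd; cc$cr <- cr
    cc$nc1 <- ncol(u1$y); cc$nc2 <- ncol(u2$y); cc$ws <- ws
    out$cache <- cc
  }
  out
}

unetBackward <- function(params, cache, dy, spec) {
  dbl <- spec$blocks == "double"
  ws <- cache$ws
  grads <- list()
  d <- cropBackward(cache$cr, arr4ToMat(dy))
  hb <- conv1Backward(cache$hd, params$head_W, d)
  grads$head_W <- hb$dW; grads$head_b <- hb$db
  dx <- hb$dx
  if (dbl) { r <- unetBlockB(cache$d2b, params, "d2b", dx, grads, ws)
             grads <- r$grads; dx <- r$dx }
  r <- unetBlockB(cache$d2a, params, "d2a", dx, grads, ws)
  grads <- r$grads; dc2 <- r$dx
  du2 <- dc2[, seq_len(cache$nc2), drop = FALSE]
  dskip1 <- dc2[, cache$nc2 + seq_len(ncol(dc2) - cache$nc2), drop = FALSE]
  ub2 <- convT2Backward(cache$u2, params$u2_W, du2)
  grads$u2_W <- ub2$dW; grads$u2_b <- ub2$db
  dx <- ub2$dx
  if (dbl) { r <- unetBlockB(cache$d1b, params, "d1b", dx, grads, ws)
             grads <- r$grads; dx <- r$dx }
  r <- unetBlockB(cache$d1a, params, "d1a", dx, grads, ws)
  grads <- r$grads; dc1 <- r$dx
  du1 <- dc1[, seq_len(cache$nc1), drop = FALSE]
  dskip2 <- dc1[, cache$nc1 + seq_len(ncol(dc1) - cache$nc1), drop = FALSE]
  ub1 <- convT2Backward(cache$u1, params$u1_W, du1)
  grads$u1_W <- ub1$dW; grads$u1_b <- ub1$db
  dx <- ub1$dx
  if (dbl) { r <- unetBlockB(cache$bb, params, "bb", dx, grads, ws)
             grads <- r$grads; dx <- r$dx }
  r <- unetBlockB(cache$ba, params, "ba", dx, grads, ws)
  grads <- r$grads
  dp2 <- maxPoolBackward(cache$p2, r$dx)
  dx <- dp2 + dskip2
  if (dbl) { r <- unetBlockB(cache$e2b, params, "e2b", dx, grads, ws)
             grads <- r$grads; dx <- r$dx }
  r <- unetBlockB(cache$e2a, params, "e2a", dx, grads, ws)
  grads <- r$grads
  dp1 <- maxPoolBackward(cache$p1, r$dx)
  dx <- dp1 + dskip1
  if (dbl) { r <- unetBlockB(cache$e1b, params, "e1b", dx, grads, ws)
             grads <- r$grads; dx <- r$dx }
  r <- unetBlockB(cache$e1a, params, "e1a", dx, grads, ws)
  r$grads
}
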