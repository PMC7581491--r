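# Layer primitives for the encoder-decoder network.  All activations are
# 4-D arrays (H, W, C, N).  Each *_fwd returns the output plus a cache; each
# *_bwd consumes the cache and the upstream gradient.  Convolutions run in
# compiled code (src/conv.cpp); everything else is vectorised R.

relu_fwd <- function(x) cpp_relu_fwd(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- batch normalisation (per channel over H, W, N) -------------------------

bn_fwd <- function(x, p, training = FALSE, momentum = 0.9, eps = 1e-5) {
  r <- cpp_bn_fwd(x, p$gamma, p$beta, p$rm, p$rv, dim(x), training, eps)
  if (!training) return(list(out = r$y, p = p, cache = NULL))
  p$rm <- momentum * p$rm + (1 - momentum) * r$mu
  p$rv <- momentum * p$rv + (1 - momentum) * r$va
  list(out = r$y, p = p,
       cache = list(xhat = r$xhat, inv_std = r$inv_std, dims = dim(x)))
}

bn_bwd <- function(dy, cache, p) {
  r <- cpp_bn_bwd(dy, cache$xhat, cache$inv_std, p$gamma, cache$dims)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

# ---- conv -> BN -> ReLU block ----------------------------------------------

conv_block_init <- function(k, cin, cout) {
  list(
    w = array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
              dim = c(k, k, cin, cout)),
    b = numeric(cout),
    gamma = rep(1, cout), beta = numeric(cout),
    rm = numeric(cout), rv = rep(1, cout)
  )
}

conv_block_fwd <- function(x, p, training = FALSE, momentum = 0.9,
                           eps = 1e-5) {
  r <- cpp_block_fwd(x, p$w, p$b, p$gamma, p$beta, p$rm, p$rv, dim(x),
                     training, eps)
  if (!training) return(list(out = r$out, p = p, cache = NULL))
  p$rm <- momentum * p$rm + (1 - momentum) * as.numeric(r$mu)
  p$rv <- momentum * p$rv + (1 - momentum) * as.numeric(r$va)
  list(out = r$out, p = p, cache = list(x = x, cxp = r$cache))
}

conv_block_bwd <- function(dy, cache, p) {
  cb <- cpp_block_bwd(cache$x, p$w, p$gamma, p$beta, dy, dim(cache$x),
                      cache$cxp)
  list(dx = cb$dx,
       g = list(w = cb$dw, b = as.numeric(cb$db),
                gamma = as.numeric(cb$dgamma), beta = as.numeric(cb$dbeta)))
}

# ---- squeeze-and-excitation ------------------------------------------------

scse_init <- function(C, reduction = 2L) {
  Cr <- if (C < reduction) C else max(1L, C %/% reduction)
  list(
    w1 = matrix(stats::rnorm(Cr * C, 0, sqrt(2 / C)), Cr, C),
    b1 = numeric(Cr),
    w2 = matrix(stats::rnorm(C * Cr, 0, sqrt(2 / Cr)), C, Cr),
    b2 = numeric(C),
    ws = array(stats::rnorm(C, 0, sqrt(2 / C)), dim = c(1, 1, C, 1)),
    bs = 0
  )
}

# broadcast helpers: s is (C, N) -> (H, W, C, N); q is (H, W, 1, N) -> over C
broadcast_cn <- function(s, d) {
  out <- array(0, d)
  for (n in seq_len(d[4]))
    out[, , , n] <- array(rep(s[, n], each = d[1] * d[2]), d[1:3])
  out
}
broadcast_hwn <- function(q, d) {
  out <- array(0, d)
  qm <- array(q, dim = c(d[1], d[2], d[4]))
  for (cc in seq_len(d[3])) out[, , cc, ] <- qm
  out
}

#' Squeeze-and-excitation recalibration of a feature map stack
#'
#' The channel path (cSE) global-average-pools each channel, passes the
#' channel descriptor through a two-layer bottleneck (reduction ratio `r`,
#' ReLU then sigmoid) and scales each channel by its gate.  The spatial path
#' (sSE) gates each spatial location by a sigmoid of a 1x1 convolution.  The
#' concurrent variant combines the two recalibrated maps elementwise
#' (`"max"` by default, `"sum"` optionally).
#'
#' @param x activation array `(H, W, C, N)`.
#' @param p parameter list from the network builder (or `scse_init`).
#' @param variant `"cSE"`, `"sSE"` or `"scSE"`.
#' @param combine `"max"` or `"sum"` for the concurrent variant.
#' @param training keep a cache for the backward pass.
#' @return `list(out, cache)`.
#' @keywords internal
scse_fwd <- function(x, p, variant = "scSE", combine = "max",
                     training = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  cache <- list(x = x, d = d, variant = variant, combine = combine)
  u_cse <- NULL; u_sse <- NULL
  if (variant %in% c("cSE", "scSE")) {
    xm <- x; dim(xm) <- c(H * W, C, N)
    z <- apply(xm, c(2, 3), mean)                     # (C, N)
    if (N == 1) z <- matrix(z, C, 1)
    a1 <- p$w1 %*% z + p$b1
    h <- pmax(a1, 0)
    a2 <- p$w2 %*% h + p$b2
    s <- sigmoid(a2)                                  # (C, N)
    sb <- broadcast_cn(s, d)
    u_cse <- x * sb
    cache[c("z", "a1", "h", "s", "sb")] <- list(z, a1, h, s, sb)
  }
  if (variant %in% c("sSE", "scSE")) {
    a <- cpp_conv2d_fwd(x, p$ws, p$bs, d)             # (H, W, 1, N)
    q <- sigmoid(a)
    qb <- broadcast_hwn(q, d)
    u_sse <- x * qb
    cache[c("q", "qb")] <- list(q, qb)
  }
  out <- switch(variant,
    cSE = u_cse,
    sSE = u_sse,
    scSE = if (combine == "max") pmax(u_cse, u_sse) else u_cse + u_sse)
  if (training && variant == "scSE" && combine == "max")
    cache$cse_wins <- u_cse >= u_sse
  if (training) cache[c("u_cse", "u_sse")] <- list(u_cse, u_sse)
  list(out = out, cache = if (training) cache else NULL)
}

scse_bwd <- function(dy, cache, p) {
  d <- cache$d; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  variant <- cache$variant
  du_cse <- du_sse <- NULL
  if (variant == "scSE") {
    if (cache$combine == "max") {
      du_cse <- dy * cache$cse_wins
      du_sse <- dy * !cache$cse_wins
    } else { du_cse <- dy; du_sse <- dy }
  } else if (variant == "cSE") du_cse <- dy else du_sse <- dy

  dx <- array(0, d)
  g <- list()
  if (!is.null(du_cse)) {
    dx <- dx + du_cse * cache$sb
    dsm <- du_cse * cache$x
    dim(dsm) <- c(H * W, C, N)
    ds <- apply(dsm, c(2, 3), sum)
    if (N == 1) ds <- matrix(ds, C, 1)
    da2 <- ds * cache$s * (1 - cache$s)
    g$w2 <- da2 %*% t(cache$h)
    g$b2 <- rowSums(da2)
    dh <- t(p$w2) %*% da2
    da1 <- dh * (cache$a1 > 0)
    g$w1 <- da1 %*% t(cache$z)
    g$b1 <- rowSums(da1)
    dz <- t(p$w1) %*% da1                             # (C, N)
    dx <- dx + broadcast_cn(dz, d) / (H * W)
  }
  if (!is.null(du_sse)) {
    dx <- dx + du_sse * cache$qb
    dqm <- du_sse * cache$x
    dq <- apply(dqm, c(1, 2, 4), sum)                 # (H, W, N)
    da <- array(dq, dim = c(H, W, 1, N)) * cache$q * (1 - cache$q)
    cb <- cpp_conv2d_bwd(cache$x, p$ws, da, d)
    dx <- dx + cb$dx
    g$ws <- cb$dw
    g$bs <- as.numeric(cb$db)
  }
  list(dx = dx, g = g)
}

# ---- dropout ----------------------------------------------------------------

dropout_fwd <- function(x, rate, training = FALSE) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(dy, cache) if (is.null(cache)) dy else dy * cache

# ---- softmax + Dice loss ----------------------------------------------------

softmax_fwd <- function(z) {
  d <- dim(z); C <- d[3]
  m <- z[, , 1, , drop = FALSE]
  for (cc in seq_len(C)[-1]) m <- pmax(m, z[, , cc, , drop = FALSE])
  e <- exp(z - broadcast_hwn(m, d))
  s <- e[, , 1, , drop = FALSE]
  for (cc in seq_len(C)[-1]) s <- s + e[, , cc, , drop = FALSE]
  e / broadcast_hwn(s, d)
}

# dL/dz for a loss gradient g = dL/dp through the channelwise softmax
softmax_bwd <- function(g, probs) {
  d <- dim(probs); C <- d[3]
  gp <- g * probs
  s <- gp[, , 1, , drop = FALSE]
  for (cc in seq_len(C)[-1]) s <- s + gp[, , cc, , drop = FALSE]
  probs * (g - broadcast_hwn(s, d))
}

#' Soft Dice loss
#'
#' Per class `c`, the soft Dice coefficient is
#' `D_c = (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)` with sums over all
#' pixels (and batch items); the loss is `1 - mean_c D_c`, in `[0, 1]`: 0 for
#' a perfect prediction, approaching 1 for a disjoint one.
#'
#' @param probs probability array `(H, W, C, N)`.
#' @param truth one-hot truth array of the same shape.
#' @param eps numerical guard (default `1e-6`).
#' @param gradient also return `dL/dprobs`.
#' @return the scalar loss, or `list(loss, grad)` when `gradient = TRUE`.
#' @export
dice_loss <- function(probs, truth, eps = 1e-6, gradient = FALSE) {
  if (!identical(dim(probs), dim(truth))) stop("shape mismatch in dice_loss")
  C <- dim(probs)[3]
  num <- den <- numeric(C)
  for (cc in seq_len(C)) {
    p <- probs[, , cc, , drop = FALSE]
    t <- truth[, , cc, , drop = FALSE]
    num[cc] <- 2 * sum(p * t) + eps
    den[cc] <- sum(p) + sum(t) + eps
  }
  loss <- 1 - mean(num / den)
  if (!gradient) return(loss)
  grad <- array(0, dim(probs))
  for (cc in seq_len(C)) {
    t <- truth[, , cc, , drop = FALSE]
    grad[, , cc, ] <- -(1 / C) * (2 * t * den[cc] - num[cc]) / den[cc]^2
  }
  list(loss = loss, grad = grad)
}

# one-hot encode an integer label matrix (values 0..C-1) to (H, W, C, 1)
one_hot_regions <- function(regions, n_classes = 3L) {
  d <- dim(regions)
  out <- array(0, c(d[1], d[2], n_classes, 1))
  for (cc in seq_len(n_classes)) out[, , cc, 1] <- regions == (cc - 1L)
  out
}
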