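#' Build the fully semantic encoder-decoder network
#'
#' Instantiates the U-Net-topology network described by a [net_config()]:
#' `n_pool` encoder levels of `convs_per_level` conv->BN->ReLU blocks with a
#' residual addition between the first and last block outputs, optional
#' squeeze-and-excitation at each level output, 2x2 stride-2 max pooling, a
#' bottleneck with 50% dropout, a mirrored decoder with skip concatenation,
#' and a final 1x1 convolution + softmax over the three region classes.
#' Spatial size is preserved throughout ("same" padding), so the output
#' probability map matches the (padded) input pixel for pixel.
#'
#' Weights are He-initialised from the current RNG stream; seed the stream
#' for reproducible networks.
#'
#' @param cfg a [net_config()].
#' @param in_channels input image channels (default 1, grayscale).
#' @return an object of class `oct_network` holding all parameters.
#' @export
build_network <- function(cfg, in_channels = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  k <- cfg$kernel
  filt <- level_filters(cfg)              # length n_pool + 1
  K <- cfg$convs_per_level

  make_level <- function(cin, cout) {
    blocks <- vector("list", K)
    blocks[[1]] <- conv_block_init(k, cin, cout)
    if (K > 1)
      for (i in 2:K) blocks[[i]] <- conv_block_init(k, cout, cout)
    lv <- list(blocks = blocks)
    if (cfg$scse != "none") lv$scse <- scse_init(cout, cfg$scse_reduction)
    lv
  }

  enc <- vector("list", cfg$n_pool)
  cin <- in_channels
  for (l in seq_len(cfg$n_pool)) {
    enc[[l]] <- make_level(cin, filt[l])
    cin <- filt[l]
  }
  bottleneck <- make_level(filt[cfg$n_pool], filt[cfg$n_pool + 1])

  dec <- vector("list", cfg$n_pool)
  for (l in seq_len(cfg$n_pool)) {         # dec[[l]] outputs at enc level l
    cbelow <- filt[l + 1]
    up <- if (cfg$upsample == "transposed") {
      list(w = array(stats::rnorm(4 * cbelow * filt[l], 0,
                                  sqrt(2 / (4 * cbelow))),
                     dim = c(2, 2, cbelow, filt[l])),
           b = numeric(filt[l]))
    } else {
      list(w = array(stats::rnorm(k * k * cbelow * filt[l], 0,
                                  sqrt(2 / (k * k * cbelow))),
                     dim = c(k, k, cbelow, filt[l])),
           b = numeric(filt[l]))
    }
    lv <- make_level(2L * filt[l], filt[l])
    lv$up <- up
    dec[[l]] <- lv
  }

  final <- list(
    w = array(stats::rnorm(filt[1] * cfg$n_classes, 0, sqrt(2 / filt[1])),
              dim = c(1, 1, filt[1], cfg$n_classes)),
    b = numeric(cfg$n_classes)
  )

  structure(list(cfg = cfg, in_channels = as.integer(in_channels),
                 enc = enc, bottleneck = bottleneck, dec = dec,
                 final = final),
            class = "oct_network")
}

#' @export
print.oct_network <- function(x, ...) {
  cat(sprintf("<oct_network: %d pooling levels, filters %s, scSE=%s, %s params, ERF %d px>\n",
              x$cfg$n_pool, paste(level_filters(x$cfg), collapse = "/"),
              x$cfg$scse, format(count_params(x), big.mark = ","),
              receptive_field(x$cfg)))
  invisible(x)
}

TRAINABLE <- c("w", "b", "gamma", "beta", "w1", "b1", "w2", "b2", "ws", "bs")

#' Number of trainable parameters of a network
#' @param net an `oct_network`.
#' @return integer count (batch-norm running statistics excluded).
#' @export
count_params <- function(net) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      nm <- names(x)
      for (i in seq_along(x)) {
        if (!is.null(nm) && nzchar(nm[i]) && nm[i] %in% c("rm", "rv", "cfg"))
          next
        if (is.numeric(x[[i]])) {
          if (is.null(nm) || !nzchar(nm[i]) || nm[i] %in% TRAINABLE)
            n <<- n + length(x[[i]])
        } else if (is.list(x[[i]])) walk(x[[i]])
      }
    }
  }
  walk(list(net$enc, net$bottleneck, net$dec, net$final))
  n
}

# ---- forward ---------------------------------------------------------------

level_fwd <- function(x, lv, cfg, training = FALSE) {
  K <- length(lv$blocks)
  outs <- vector("list", K)
  caches <- vector("list", K)
  cur <- x
  for (i in seq_len(K)) {
    r <- conv_block_fwd(cur, lv$blocks[[i]], training)
    lv$blocks[[i]] <- r$p
    outs[[i]] <- r$out
    caches[[i]] <- r$cache
    cur <- r$out
  }
  out <- if (K > 1) outs[[1]] + outs[[K]] else outs[[1]]
  sc <- NULL
  if (!is.null(lv$scse)) {
    r <- scse_fwd(out, lv$scse, variant = cfg$scse,
                  combine = cfg$scse_combine, training = training)
    out <- r$out
    sc <- r$cache
  }
  list(out = out, lv = lv,
       cache = if (training) list(blocks = caches, scse = sc) else NULL)
}

level_bwd <- function(dy, cache, lv) {
  g <- list(blocks = vector("list", length(lv$blocks)))
  if (!is.null(lv$scse)) {
    r <- scse_bwd(dy, cache$scse, lv$scse)
    dy <- r$dx
    g$scse <- r$g
  }
  K <- length(lv$blocks)
  d_first_extra <- if (K > 1) dy else NULL   # residual add: grad to block 1
  cur <- dy
  for (i in rev(seq_len(K))) {
    r <- conv_block_bwd(cur, cache$blocks[[i]], lv$blocks[[i]])
    g$blocks[[i]] <- r$g
    cur <- r$dx
    if (i == 2 && !is.null(d_first_extra)) cur <- cur + d_first_extra
  }
  list(dx = cur, g = g)
}

nearest_up_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

nearest_up_bwd <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1, d[1], by = 2); j1 <- seq(1, d[2], by = 2)
  dy[i1, j1, , , drop = FALSE] + dy[i1 + 1, j1, , , drop = FALSE] +
    dy[i1, j1 + 1, , , drop = FALSE] + dy[i1 + 1, j1 + 1, , , drop = FALSE]
}

#' Forward pass of the segmentation network
#'
#' @param net an `oct_network`.
#' @param x input array `(H, W, C, N)`; `H` and `W` must be divisible by
#'   `2^n_pool` (use [pad_top()] to guarantee this).
#' @param training when `TRUE`, uses batch statistics, applies bottleneck
#'   dropout (from the current RNG stream) and retains the caches needed by
#'   [network_backward()]; batch-norm running statistics are updated on the
#'   returned network.
#' @return `list(probs, logits, net, cache)`; `probs` is `(H, W, n_classes,
#'   N)` with a softmax over classes at every pixel.
#' @export
network_forward <- function(net, x, training = FALSE) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4) stop("`x` must be a 4-D (H,W,C,N) array")
  div <- 2^net$cfg$n_pool
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop(sprintf("input %dx%d not divisible by 2^n_pool = %d; pad the image (pad_top) to a multiple",
                 d[1], d[2], div))
  cfg <- net$cfg
  cache <- list(enc = vector("list", cfg$n_pool),
                pool = vector("list", cfg$n_pool),
                dec = vector("list", cfg$n_pool))
  skips <- vector("list", cfg$n_pool)
  cur <- x
  for (l in seq_len(cfg$n_pool)) {
    r <- level_fwd(cur, net$enc[[l]], cfg, training)
    net$enc[[l]] <- r$lv
    cache$enc[[l]] <- r$cache
    skips[[l]] <- r$out
    mp <- cpp_maxpool_fwd(r$out, dim(r$out))
    cache$pool[[l]] <- list(idx = mp$idx, indim = dim(r$out))
    cur <- mp$y
  }
  r <- level_fwd(cur, net$bottleneck, cfg, training)
  net$bottleneck <- r$lv
  cache$bottleneck <- r$cache
  dp <- dropout_fwd(r$out, cfg$bottleneck_dropout, training)
  cache$dropout <- dp$cache
  cur <- dp$out
  for (l in rev(seq_len(cfg$n_pool))) {
    lv <- net$dec[[l]]
    if (cfg$upsample == "transposed") {
      up <- cpp_upconv_fwd(cur, lv$up$w, lv$up$b, dim(cur))
      upc <- list(x = cur)
    } else {
      nu <- nearest_up_fwd(cur)
      up <- cpp_conv2d_fwd(nu, lv$up$w, lv$up$b, dim(nu))
      upc <- list(x = cur, nu = nu)
    }
    sk <- skips[[l]]
    cat_in <- array(0, dim(sk) + c(0, 0, dim(up)[3], 0))
    nsk <- dim(sk)[3]
    cat_in[, , seq_len(nsk), ] <- sk
    cat_in[, , nsk + seq_len(dim(up)[3]), ] <- up
    r <- level_fwd(cat_in, lv, cfg, training)
    r$lv$up <- lv$up
    net$dec[[l]] <- r$lv
    cache$dec[[l]] <- list(level = r$cache, up = upc, nsk = nsk,
                           catdim = dim(cat_in))
    cur <- r$out
  }
  logits <- cpp_conv2d_fwd(cur, net$final$w, net$final$b, dim(cur))
  probs <- softmax_fwd(logits)
  cache$final_in <- if (training) cur else NULL
  cache$probs <- if (training) probs else NULL
  list(probs = probs, logits = logits, net = net,
       cache = if (training) cache else NULL)
}

#' Backward pass: gradients of a loss on the softmax probabilities
#'
#' @param net the `oct_network` used in the forward pass.
#' @param cache the cache from `network_forward(..., training = TRUE)`.
#' @param dprobs gradient of the loss with respect to `probs`.
#' @return a nested gradient tree parallel to the network's parameters.
#' @export
network_backward <- function(net, cache, dprobs) {
  cfg <- net$cfg
  dz <- softmax_bwd(dprobs, cache$probs)
  fb <- cpp_conv2d_bwd(cache$final_in, net$final$w, dz, dim(cache$final_in))
  g <- list(final = list(w = fb$dw, b = as.numeric(fb$db)),
            dec = vector("list", cfg$n_pool),
            enc = vector("list", cfg$n_pool))
  cur <- fb$dx
  dskip <- vector("list", cfg$n_pool)
  for (l in seq_len(cfg$n_pool)) {           # decoder ran deep->shallow; undo shallow->deep
    dc <- cache$dec[[l]]
    lv <- net$dec[[l]]
    r <- level_bwd(cur, dc$level, lv)
    nsk <- dc$nsk
    dcat <- r$dx
    dskip[[l]] <- dcat[, , seq_len(nsk), , drop = FALSE]
    dup <- dcat[, , nsk + seq_len(dc$catdim[3] - nsk), , drop = FALSE]
    if (cfg$upsample == "transposed") {
      ub <- cpp_upconv_bwd(dc$up$x, lv$up$w, dup, dim(dc$up$x))
      cur <- ub$dx
    } else {
      ub <- cpp_conv2d_bwd(dc$up$nu, lv$up$w, dup, dim(dc$up$nu))
      cur <- nearest_up_bwd(ub$dx)
    }
    r$g$up <- list(w = ub$dw, b = as.numeric(ub$db))
    g$dec[[l]] <- r$g
  }
  cur <- dropout_bwd(cur, cache$dropout)
  r <- level_bwd(cur, cache$bottleneck, net$bottleneck)
  g$bottleneck <- r$g
  cur <- r$dx
  for (l in rev(seq_len(cfg$n_pool))) {
    pl <- cache$pool[[l]]
    dpool <- cpp_maxpool_bwd(pl$idx, cur, pl$indim)
    dlevel <- dpool + dskip[[l]]
    r <- level_bwd(dlevel, cache$enc[[l]], net$enc[[l]])
    g$enc[[l]] <- r$g
    cur <- r$dx
  }
  g
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function() list(t = 0L, m = NULL, v = NULL)

# walk params/grads trees in parallel, applying the Adam update to every
# trainable numeric leaf (rm/rv and cfg are skipped; missing grads leave the
# leaf unchanged)
adam_step <- function(net, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  upd <- function(p, g, m, v) {
    if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, m = m, v = v))
      if (is.null(m)) { m <- p * 0; v <- p * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      return(list(p = p, m = m, v = v))
    }
    if (!is.list(p)) return(list(p = p, m = m, v = v))
    nm <- names(p)
    if (is.null(m)) { m <- vector("list", length(p)); v <- m }
    for (i in seq_along(p)) {
      if (!is.null(nm) && nm[i] %in% c("rm", "rv", "cfg", "in_channels")) next
      gi <- if (is.list(g) && length(g) >= 1) {
        if (!is.null(nm) && nzchar(nm[i] %||% "")) g[[nm[i]]] else
          if (i <= length(g)) g[[i]] else NULL
      } else NULL
      r <- upd(p[[i]], gi, m[[i]], v[[i]])
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  parts <- list(enc = net$enc, bottleneck = net$bottleneck, dec = net$dec,
                final = net$final)
  r <- upd(parts, grads[c("enc", "bottleneck", "dec", "final")],
           state$m, state$v)
  net$enc <- r$p$enc; net$bottleneck <- r$p$bottleneck
  net$dec <- r$p$dec; net$final <- r$p$final
  state$m <- r$m; state$v <- r$v
  list(net = net, state = state)
}
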