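test_that("receptive field calculator reproduces the architecture family", {
  expect_identical(receptive_field(net_config(n_pool = 4)), 202L)
  expect_identical(receptive_field(net_config(n_pool = 5)), 410L)
  # no pooling, three 3x3 convolutions: 1 + 3 * 2 = 7
  expect_identical(receptive_field(list(n_pool = 0L, convs_per_level = 3L,
                                        kernel = 3L)), 7L)
  # monotone in depth and convolutions per level
  expect_lt(receptive_field(net_config(n_pool = 4)),
            receptive_field(net_config(n_pool = 5)))
  expect_lt(receptive_field(net_config(n_pool = 4, convs_per_level = 2)),
            receptive_field(net_config(n_pool = 4, convs_per_level = 3)))
})

test_that("network preserves spatial shape and emits per-pixel softmax", {
  set.seed(1)
  net <- build_network(net_config(n_pool = 4, scse = "scSE"))
  x <- array(runif(144 * 256), c(144, 256, 1, 1))
  fw <- network_forward(net, x)
  expect_identical(dim(fw$probs), c(144L, 256L, 3L, 1L))
  sums <- fw$probs[, , 1, 1] + fw$probs[, , 2, 1] + fw$probs[, , 3, 1]
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(fw$probs >= 0))
  # deterministic given fixed weights
  fw2 <- network_forward(net, x)
  expect_identical(fw$probs, fw2$probs)
  # indivisible input rejected with a padding hint
  expect_error(network_forward(net, array(0, c(100, 256, 1, 1))), "pad")
})

test_that("filter schedule doubles from eight after every pooling layer", {
  expect_identical(level_filters(net_config(n_pool = 4)),
                   c(8L, 16L, 32L, 64L, 128L))
  net <- build_network(net_config(n_pool = 4))
  enc_out <- vapply(net$enc, function(l) dim(l$blocks[[1]]$w)[4], integer(1))
  expect_identical(enc_out, c(8L, 16L, 32L, 64L))
  expect_identical(dim(net$bottleneck$blocks[[1]]$w)[4], 128L)
})

test_that("squeeze-and-excitation blocks add parameters", {
  set.seed(2)
  n0 <- count_params(build_network(net_config(scse = "none")))
  n1 <- count_params(build_network(net_config(scse = "scSE")))
  expect_gt(n1, n0)
})

test_that("scse gating behaves per its algebra", {
  set.seed(3)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4, 1))
  p <- octseg:::scse_init(4L, 2L)
  # force all gates to ~1: both paths become the identity
  p1 <- p
  p1$w2[] <- 0; p1$b2[] <- 40                     # sigmoid(40) ~ 1
  p1$ws[] <- 0; p1$bs <- 40
  r <- octseg:::scse_fwd(x, p1, variant = "scSE", combine = "max")
  expect_equal(r$out, x, tolerance = 1e-12)
  # cSE gates ~0 with max combination: output equals the sSE path
  p0 <- p
  p0$w2[] <- 0; p0$b2[] <- -40
  r2 <- octseg:::scse_fwd(x, p0, variant = "scSE", combine = "max")
  rs <- octseg:::scse_fwd(x, p0, variant = "sSE")
  expect_equal(r2$out, rs$out, tolerance = 1e-12)
  # constant input: the channel gate is identical across spatial positions
  xc <- array(rep(c(1, 2, 3, 4), each = 64), c(8, 8, 4, 1))
  rc <- octseg:::scse_fwd(xc, p, variant = "cSE")
  gate <- rc$out / xc
  for (cc in 1:4) expect_lt(diff(range(gate[, , cc, 1])), 1e-12)
  # channel count below the reduction ratio falls back to ratio 1
  p_small <- octseg:::scse_init(1L, 2L)
  expect_identical(dim(p_small$w1), c(1L, 1L))
})

test_that("dice loss matches hand evaluation and spans [0, 1]", {
  # perfect prediction
  t <- array(0, c(4, 4, 3, 1)); t[, , 1, ][1:2, ] <- 1; t[, , 2, ][3, ] <- 1
  t[, , 3, ][4, ] <- 1
  expect_equal(dice_loss(t, t), 0, tolerance = 1e-6)
  # fully disjoint prediction: zero intersection in every class
  expect_equal(dice_loss(1 - t, t), 1, tolerance = 1e-4)
  # 2x2 single-class truth with uniform probabilities 1/3, by direct formula
  tr <- array(0, c(2, 2, 3, 1)); tr[, , 2, ] <- 1
  pu <- array(1 / 3, c(2, 2, 3, 1))
  d_c <- c((2 * 0 + 1e-6) / (4 / 3 + 0 + 1e-6),
           (2 * 4 / 3 + 1e-6) / (4 / 3 + 4 + 1e-6),
           (2 * 0 + 1e-6) / (4 / 3 + 0 + 1e-6))
  expect_equal(dice_loss(pu, tr), 1 - mean(d_c), tolerance = 1e-9)
  expect_equal(dice_loss(pu, tr), ref_dice_loss(pu, tr), tolerance = 1e-12)
})

test_that("fused conv-bn-relu block matches the reference composition", {
  set.seed(4)
  x <- array(rnorm(12 * 10 * 3 * 2), c(12, 10, 3, 2))
  p <- octseg:::conv_block_init(3, 3, 5)
  p$gamma <- runif(5, 0.5, 1.5); p$beta <- rnorm(5, 0, 0.2)
  r <- octseg:::conv_block_fwd(x, p, training = TRUE)
  z_ref <- ref_conv2d(x, p$w, p$b)
  y_ref <- ref_bn_relu(z_ref, p$gamma, p$beta)
  expect_equal(r$out, y_ref, tolerance = 1e-4)
  # inference mode uses the running statistics
  p2 <- p; p2$rm <- rnorm(5); p2$rv <- runif(5, 0.5, 2)
  ri <- octseg:::conv_block_fwd(x, p2, training = FALSE)
  z <- ref_conv2d(x, p2$w, p2$b)
  yi <- z
  for (cc in 1:5) yi[, , cc, ] <- pmax(p2$gamma[cc] *
    (z[, , cc, ] - p2$rm[cc]) / sqrt(p2$rv[cc] + 1e-5) + p2$beta[cc], 0)
  expect_equal(ri$out, yi, tolerance = 1e-4)
})

test_that("block backward matches double-precision finite differences", {
  set.seed(5)
  x <- array(rnorm(8 * 6 * 2), c(8, 6, 2, 1))
  p <- octseg:::conv_block_init(3, 2, 3)
  p$gamma <- runif(3, 0.8, 1.2)
  dy <- array(rnorm(8 * 6 * 3), c(8, 6, 3, 1))
  fw <- octseg:::conv_block_fwd(x, p, training = TRUE)
  bw <- octseg:::conv_block_bwd(dy, fw$cache, p)
  lossf <- function(pp, xx) sum(octseg:::conv_block_fwd(xx, pp,
                                                        training = TRUE)$out * dy)
  eps <- 1e-3                                     # float kernels: moderate step
  for (nm in c("w", "gamma", "beta")) {
    v <- p[[nm]]
    for (i in sample(length(v), min(5, length(v)))) {
      pp <- p; pm <- p
      pp[[nm]][i] <- v[i] + eps
      pm[[nm]][i] <- v[i] - eps
      num <- (lossf(pp, x) - lossf(pm, x)) / (2 * eps)
      expect_equal(bw$g[[nm]][i], num, tolerance = 5e-2)
    }
  }
  for (i in sample(length(x), 5)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps; xm[i] <- x[i] - eps
    num <- (lossf(p, xp) - lossf(p, xm)) / (2 * eps)
    expect_equal(bw$dx[i], num, tolerance = 5e-2)
  }
})

test_that("whole-network gradient agrees with the directional derivative", {
  set.seed(6)
  cfg <- net_config(n_pool = 4, base_filters = 2, convs_per_level = 3,
                    scse = "scSE", scse_combine = "sum",
                    bottleneck_dropout = 0)
  net <- build_network(cfg)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  truth <- array(0, c(16, 16, 3, 1))
  truth[, , 1, ][1:5, ] <- 1; truth[, , 2, ][6:10, ] <- 1
  truth[, , 3, ][11:16, ] <- 1
  lossfun <- function(n) dice_loss(network_forward(n, x,
                                                   training = TRUE)$probs, truth)
  fw <- network_forward(net, x, training = TRUE)
  dl <- dice_loss(fw$probs, truth, gradient = TRUE)
  g <- network_backward(net, fw$cache, dl$grad)
  add_dir <- function(p, gg, s) {
    if (is.numeric(p) && is.numeric(gg)) return(p + s * gg)
    if (!is.list(p) || is.null(gg)) return(p)
    nm <- names(p)
    for (i in seq_along(p)) {
      gi <- if (!is.null(nm)) gg[[nm[i]]] else gg[[i]]
      if (!is.null(gi)) p[[i]] <- add_dir(p[[i]], gi, s)
    }
    p
  }
  g2 <- 0
  acc <- function(gg) {
    if (is.numeric(gg)) g2 <<- g2 + sum(gg^2)
    else if (is.list(gg)) for (e in gg) acc(e)
  }
  acc(g)
  eps <- 1e-3 / sqrt(g2)
  np <- net; nm2 <- net
  for (pt in c("enc", "bottleneck", "dec", "final")) {
    np[[pt]] <- add_dir(net[[pt]], g[[pt]], eps)
    nm2[[pt]] <- add_dir(net[[pt]], g[[pt]], -eps)
  }
  num <- (lossfun(np) - lossfun(nm2)) / (2 * eps)
  expect_equal(num, g2, tolerance = 0.1)          # curvature-limited check
})

test_that("softmax backward matches finite differences of the loss", {
  set.seed(7)
  z <- array(rnorm(4 * 3 * 3), c(4, 3, 3, 1))
  truth <- array(0, c(4, 3, 3, 1)); truth[, , 1, ][1:2, ] <- 1
  truth[, , 2, ][3, ] <- 1; truth[, , 3, ][4, ] <- 1
  p <- octseg:::softmax_fwd(z)
  dl <- dice_loss(p, truth, gradient = TRUE)
  dz <- octseg:::softmax_bwd(dl$grad, p)
  eps <- 1e-6
  for (i in sample(length(z), 8)) {
    zp <- z; zm <- z
    zp[i] <- z[i] + eps; zm[i] <- z[i] - eps
    num <- (dice_loss(octseg:::softmax_fwd(zp), truth) -
              dice_loss(octseg:::softmax_fwd(zm), truth)) / (2 * eps)
    expect_equal(dz[i], num, tolerance = 1e-4)
  }
})
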