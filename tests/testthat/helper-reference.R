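# Independent reference implementations used as oracles: all plain double
# precision R, written directly from the defining formulas, never calling
# the package's compiled kernels.

ref_conv2d <- function(x, w, b) {
  d <- dim(x); k <- dim(w)[1]; pad <- (k - 1) / 2; cout <- dim(w)[4]
  y <- array(0, c(d[1], d[2], cout, d[4]))
  for (n in seq_len(d[4])) for (o in seq_len(cout))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      acc <- b[o]
      for (cc in seq_len(d[3])) for (di in seq_len(k)) for (dj in seq_len(k)) {
        ii <- i + di - 1 - pad; jj <- j + dj - 1 - pad
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
          acc <- acc + x[ii, jj, cc, n] * w[di, dj, cc, o]
      }
      y[i, j, o, n] <- acc
    }
  y
}

ref_bn_relu <- function(z, gamma, beta, eps = 1e-5) {
  d <- dim(z); C <- d[3]
  y <- z
  for (cc in seq_len(C)) {
    s <- z[, , cc, , drop = FALSE]
    m <- mean(s); v <- mean((s - m)^2)
    y[, , cc, ] <- pmax(gamma[cc] * (s - m) / sqrt(v + eps) + beta[cc], 0)
  }
  y
}

ref_dice_loss <- function(probs, truth, eps = 1e-6) {
  C <- dim(probs)[3]
  d <- vapply(seq_len(C), function(cc) {
    p <- probs[, , cc, ]; t <- truth[, , cc, ]
    (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  }, numeric(1))
  1 - mean(d)
}

# exhaustive minimum-cost monotone 3-neighbour path through a boundary
# probability map, with probability-1 dummy entry/exit columns
ref_min_path_cost <- function(p) {
  H <- nrow(p); W <- ncol(p)
  best <- Inf
  rec <- function(col, row, cost) {
    if (cost >= best) return()
    if (col == W) {
      tot <- cost + (1 - p[row, W])
      if (tot < best) best <<- tot
      return()
    }
    for (dr in c(0, -1, 1)) {
      r2 <- row + dr
      if (r2 >= 1 && r2 <= H)
        rec(col + 1, r2, cost + 2 - p[row, col] - p[r2, col + 1])
    }
  }
  for (r0 in seq_len(H)) rec(1, r0, 1 - p[r0, 1])
  best
}

# a noise-free phantom configuration used across tests (overridable)
clean_phantom_config <- function(...) {
  do.call(phantom_config, utils::modifyList(
    list(n_flecks = 0L, speckle_looks = 0, n_shadows = 0L, n_lesions = 0L,
         undulation_amp_px = 0, pit_depth_um = 0), list(...)))
}

# tiny geometry for fast training tests: 64 x 64 images, 3 scans
tiny_phantom_config <- function(...) {
  do.call(phantom_config, utils::modifyList(
    list(height_px = 64L, width_px = 64L, n_scans = 3L,
         lateral_res_um = 137.5, axial_res_um = 30.2,
         scan_spacing_um = 2000, lesion_width_px = 16L), list(...)))
}
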