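as_pixel_matrix <- function(image) {
  if (inherits(image, "bscan")) image$pixels else {
    if (!is.matrix(image)) stop("`image` must be a matrix or a bscan")
    image
  }
}

rewrap_image <- function(image, pixels) {
  if (inherits(image, "bscan")) {
    image$pixels <- pixels
    image$height_px <- nrow(pixels)
    image$width_px <- ncol(pixels)
    image
  } else pixels
}

#' A-scan attenuation-compensation contrast enhancement
#'
#' Per-column (A-scan) energy compensation: each pixel's intensity, raised to
#' the energy exponent `n`, is divided by twice the cumulative energy from
#' that depth downward,
#' \deqn{E(i,j) = I(i,j)^n / (2 \sum_{k \ge i} I(k,j)^n + \epsilon),}
#' which equalises the signal across depth and sharpens the RPE/Bruch's
#' membrane complex.  The result is rescaled linearly to `[0, 255]`.  The
#' operation is deterministic and strictly column-local.  The exact constants
#' of the originally published attenuation filter are not restated here; the
#' exponent is exposed as a parameter (default 2).
#'
#' @param image a [bscan()] or numeric matrix.
#' @param energy_exponent positive exponent `n`.
#' @return same type as `image`.
#' @export
enhance_contrast <- function(image, energy_exponent = 2) {
  stopifnot_scalar_num(energy_exponent, "energy_exponent", lo = 1e-12)
  px <- as_pixel_matrix(image)
  if (length(px) == 0) stop("empty image")
  en <- px^energy_exponent
  # reversed cumulative sum down each column: sum_{k >= i} I(k,j)^n
  tail_energy <- apply(en, 2, function(col) rev(cumsum(rev(col))))
  out <- en / (2 * tail_energy + 1e-12)
  mx <- max(out)
  if (mx > 0) out <- out / mx * 255
  rewrap_image(image, out)
}

#' Zero-pad the top of a B-scan
#'
#' Adds `n_rows` rows of zeros above the image (class 0, vitreous+padding,
#' in region maps) and shifts boundary rows down by `n_rows`.  The default of
#' 16 rows makes a 128-row desk image (or a 496-row clinical image after its
#' own padding choice) divisible by `2^4` for the pooling pyramid.
#'
#' @param image a [bscan()] or matrix.
#' @param n_rows number of zero rows to add (>= 0).
#' @param boundaries optional [boundary_set()] to shift along.
#' @return the padded image, or `list(image, boundaries)` when `boundaries`
#'   is supplied.
#' @export
pad_top <- function(image, n_rows = 16L, boundaries = NULL) {
  if (n_rows < 0) stop("n_rows must be >= 0")
  px <- as_pixel_matrix(image)
  out <- rbind(matrix(0, n_rows, ncol(px)), px)
  img <- rewrap_image(image, out)
  if (is.null(boundaries)) return(img)
  b <- boundary_set(boundaries$ilm + n_rows, boundaries$rpe + n_rows,
                    boundaries$valid_start, boundaries$valid_end,
                    height_px = nrow(out))
  list(image = img, boundaries = b)
}

#' Clean a scan by retaining a column range
#'
#' Emulates the manual cleaning of partially truncated scans: pixels outside
#' the inclusive 0-based column range `[start, end]` are zeroed, boundary
#' rows outside the range are repeated and flattened from the nearest
#' retained endpoint, and the valid range is recorded on the boundary set.
#'
#' @param image a [bscan()] or matrix.
#' @param boundaries a [boundary_set()].
#' @param start,end inclusive 0-based column range to retain.
#' @return `list(image, boundaries)`.
#' @export
clean_scan <- function(image, boundaries, start, end) {
  px <- as_pixel_matrix(image)
  w <- ncol(px)
  if (start > end) stop("start must be <= end")
  if (start < 0 || end >= w) stop("column range outside image")
  s1 <- start + 1L; e1 <- end + 1L          # 1-based matrix columns
  if (s1 > 1) px[, seq_len(s1 - 1L)] <- 0
  if (e1 < w) px[, (e1 + 1L):w] <- 0
  ilm <- boundaries$ilm; rpe <- boundaries$rpe
  if (s1 > 1) { ilm[seq_len(s1 - 1L)] <- ilm[s1]; rpe[seq_len(s1 - 1L)] <- rpe[s1] }
  if (e1 < w) { ilm[(e1 + 1L):w] <- ilm[e1]; rpe[(e1 + 1L):w] <- rpe[e1] }
  list(image = rewrap_image(image, px),
       boundaries = boundary_set(ilm, rpe, valid_start = start,
                                 valid_end = end))
}

#' Augmentation configuration
#'
#' Training-time augmentation presents each sample as exactly one of four
#' cases: unchanged, flipped left-right, noisy, or flipped and noisy (default
#' probability 1/4 each).  Noise is i.i.d. zero-mean Gaussian per pixel with
#' a variance drawn uniformly from `var_range` at each presentation, and the
#' result is clipped to `[0, 255]`.  Flips mirror both image columns and
#' boundary arrays; noise never moves boundaries.
#'
#' @param p numeric vector of 4 case probabilities summing to 1, in the order
#'   unchanged / flipped / noisy / flipped+noisy.
#' @param var_range length-2 variance range (default `c(250, 1000)`).
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(p = c(0.25, 0.25, 0.25, 0.25),
                           var_range = c(250, 1000)) {
  if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("`p` must be 4 non-negative probabilities summing to 1")
  if (length(var_range) != 2 || var_range[1] <= 0 || var_range[1] > var_range[2])
    stop("`var_range` must be positive with low <= high")
  structure(list(p = p, var_range = var_range), class = "augment_config")
}

#' Apply one augmentation case to a sample
#'
#' @param image a [bscan()] or matrix.
#' @param boundaries optional [boundary_set()] mirrored along with flips.
#' @param cfg an [augment_config()].
#' @param case optional forced case: one of `"unchanged"`, `"flipped"`,
#'   `"noisy"`, `"flipped_noisy"`; when `NULL` a case is drawn from `cfg$p`
#'   using the current RNG stream.
#' @return `list(image, boundaries, case, variance)` (`variance` is `NA` for
#'   noise-free cases).
#' @export
augment <- function(image, boundaries = NULL, cfg = augment_config(),
                    case = NULL) {
  cases <- c("unchanged", "flipped", "noisy", "flipped_noisy")
  if (is.null(case)) {
    case <- cases[findInterval(stats::runif(1), cumsum(cfg$p),
                               rightmost.closed = TRUE) + 1L]
  }
  case <- match.arg(case, cases)
  px <- as_pixel_matrix(image)
  b <- boundaries
  variance <- NA_real_
  if (case %in% c("flipped", "flipped_noisy")) {
    px <- px[, ncol(px):1, drop = FALSE]
    if (!is.null(b)) {
      w <- length(b$ilm)
      b <- boundary_set(rev(b$ilm), rev(b$rpe),
                        valid_start = w - 1L - b$valid_end,
                        valid_end = w - 1L - b$valid_start, validate = FALSE)
    }
  }
  if (case %in% c("noisy", "flipped_noisy")) {
    variance <- stats::runif(1, cfg$var_range[1], cfg$var_range[2])
    px <- px + matrix(stats::rnorm(length(px), 0, sqrt(variance)),
                      nrow(px), ncol(px))
    px <- pmin(pmax(px, 0), 255)
  }
  list(image = rewrap_image(image, px), boundaries = b, case = case,
       variance = variance)
}

#' Rasterise boundaries to a 3-class region map
#'
#' Per column: rows above `floor(ilm)` are class 0 (vitreous + padding),
#' rows from `floor(ilm)` up to but excluding `floor(rpe)` are class 1
#' (retina), and rows from `floor(rpe)` down are class 2 (choroid + sclera).
#'
#' @param boundaries a [boundary_set()].
#' @param height,width image size in pixels.
#' @return integer matrix of labels in `{0, 1, 2}`.
#' @export
boundaries_to_regions <- function(boundaries, height, width) {
  if (length(boundaries$ilm) != width)
    stop("boundary width does not match `width`")
  if (any(boundaries$ilm < 0) || any(boundaries$rpe > height - 1) ||
      any(boundaries$rpe < boundaries$ilm))
    stop("boundaries outside image or out of order")
  ilm_f <- matrix(floor(boundaries$ilm), height, width, byrow = TRUE)
  rpe_f <- matrix(floor(boundaries$rpe), height, width, byrow = TRUE)
  rmat <- matrix(seq_len(height) - 1, height, width)
  reg <- matrix(0L, height, width)
  reg[rmat >= ilm_f] <- 1L
  reg[rmat >= rpe_f] <- 2L
  reg
}

#' Recover boundary rows from a region map
#'
#' Inverse of [boundaries_to_regions()] up to `floor()`: per column, the ILM
#' is the first row with class >= 1 and the RPE base the first row with
#' class 2 (0-based rows).
#'
#' @param regions integer matrix of labels in `{0, 1, 2}`.
#' @return a [boundary_set()] with integer rows.
#' @export
regions_to_boundaries <- function(regions) {
  h <- nrow(regions)
  ilm <- apply(regions, 2, function(col) {
    i <- which(col >= 1L)[1]
    if (is.na(i)) h else i - 1L
  })
  rpe <- apply(regions, 2, function(col) {
    i <- which(col == 2L)[1]
    if (is.na(i)) h else i - 1L
  })
  boundary_set(ilm, rpe, validate = FALSE)
}
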