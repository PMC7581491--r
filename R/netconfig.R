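#' Network architecture configuration
#'
#' Hyperparameters of the fully semantic encoder-decoder family: a U-Net
#' topology whose levels each hold three 3x3 convolution blocks
#' (conv -> batch norm -> ReLU) with a residual addition between the first
#' and last block outputs, 2x2 stride-2 max pooling, filter count doubling
#' after every pooling layer from a base of 8, optional squeeze-and-excitation
#' recalibration at each level's output, and 50% dropout at the bottleneck.
#'
#' @param n_pool number of pooling layers (4 or 5).
#' @param base_filters filters in the first encoder level (default 8).
#' @param convs_per_level convolution blocks per level (default 3).
#' @param kernel square convolution kernel size (default 3).
#' @param scse squeeze-and-excitation variant at each level output:
#'   `"none"`, `"cSE"` (channel), `"sSE"` (spatial) or `"scSE"` (concurrent).
#' @param scse_reduction channel reduction ratio of the cSE bottleneck
#'   (default 2; levels with fewer channels fall back to ratio 1).
#' @param scse_combine how the two concurrent recalibrations are merged:
#'   elementwise `"max"` (default) or `"sum"`.
#' @param bottleneck_dropout dropout rate at the bottleneck (default 0.5).
#' @param n_classes output classes (default 3: vitreous+padding, retina,
#'   choroid+sclera).
#' @param upsample decoder upsampling: `"transposed"` (2x2 stride-2
#'   transposed convolution, default) or `"nearest"` (nearest-neighbour
#'   followed by a 3x3 convolution).
#' @return an object of class `net_config`.
#' @export
net_config <- function(n_pool = 4L, base_filters = 8L, convs_per_level = 3L,
                       kernel = 3L, scse = c("none", "cSE", "sSE", "scSE"),
                       scse_reduction = 2L, scse_combine = c("max", "sum"),
                       bottleneck_dropout = 0.5, n_classes = 3L,
                       upsample = c("transposed", "nearest")) {
  if (!n_pool %in% c(4L, 5L)) stop("n_pool must be 4 or 5")
  if (base_filters < 1 || convs_per_level < 1) stop("invalid filter/conv counts")
  if (kernel %% 2 != 1) stop("kernel must be odd")
  stopifnot_scalar_num(bottleneck_dropout, "bottleneck_dropout", 0, 1)
  structure(list(
    n_pool = as.integer(n_pool), base_filters = as.integer(base_filters),
    convs_per_level = as.integer(convs_per_level), kernel = as.integer(kernel),
    scse = match.arg(scse), scse_reduction = as.integer(scse_reduction),
    scse_combine = match.arg(scse_combine),
    bottleneck_dropout = bottleneck_dropout, n_classes = as.integer(n_classes),
    upsample = match.arg(upsample)
  ), class = "net_config")
}

#' Filters per encoder level (bottleneck included)
#' @param cfg a [net_config()].
#' @return integer vector of length `n_pool + 1`.
#' @export
level_filters <- function(cfg) as.integer(cfg$base_filters * 2^(0:cfg$n_pool))

#' Analytic effective receptive field at the bottleneck output
#'
#' Iterates the standard receptive-field recursion
#' \code{r <- r + (k - 1) * j} over the encoder layers, where `j` is the
#' running product of strides: each of the `convs_per_level` 3x3 convolutions
#' per encoder level grows the field by `2 j`, each 2x2 stride-2 pooling
#' grows it by `j` and doubles `j`, and the bottleneck convolutions are
#' counted last.
#' With the default architecture this gives a side length of 202 pixels for
#' four pooling layers and 410 for five.
#'
#' @param cfg a [net_config()].
#' @param bottleneck_convs convolutions in the bottleneck (defaults to
#'   `convs_per_level`).
#' @return integer receptive-field side length in pixels.
#' @export
receptive_field <- function(cfg, bottleneck_convs = cfg$convs_per_level) {
  r <- 1; j <- 1
  k <- cfg$kernel
  for (level in seq_len(cfg$n_pool)) {
    for (cv in seq_len(cfg$convs_per_level)) r <- r + (k - 1) * j
    r <- r + (2 - 1) * j        # 2x2 pool
    j <- j * 2
  }
  for (cv in seq_len(bottleneck_convs)) r <- r + (k - 1) * j
  as.integer(r)
}
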