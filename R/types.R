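#' OCT B-scan container
#'
#' A single grayscale OCT slice together with its acquisition geometry and
#' identifiers.  Pixel rows run from the vitreous (top) down through the
#' retina into the choroid; columns are lateral position.
#'
#' @param pixels numeric matrix (rows = depth, columns = lateral), values in
#'   `[0, 255]`.
#' @param lateral_res_um microns per column (Spectralis-like default 5.7).
#' @param axial_res_um microns per row (default 3.9).
#' @param scan_spacing_um microns between adjacent B-scans of a volume
#'   (default 119).
#' @param participant_id,eye,visit,scan_index identifiers; `scan_index` is the
#'   0-based position of the slice within its volume.
#' @return an object of class `bscan`.
#' @export
bscan <- function(pixels, lateral_res_um = 5.7, axial_res_um = 3.9,
                  scan_spacing_um = 119, participant_id = NA_character_,
                  eye = "OD", visit = 1L, scan_index = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  stopifnot_scalar_num(lateral_res_um, "lateral_res_um", lo = 1e-9)
  stopifnot_scalar_num(axial_res_um, "axial_res_um", lo = 1e-9)
  stopifnot_scalar_num(scan_spacing_um, "scan_spacing_um", lo = 1e-9)
  structure(list(
    pixels = pixels,
    height_px = nrow(pixels), width_px = ncol(pixels),
    lateral_res_um = lateral_res_um, axial_res_um = axial_res_um,
    scan_spacing_um = scan_spacing_um,
    participant_id = participant_id, eye = eye,
    visit = visit, scan_index = scan_index
  ), class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan %s eye=%s visit=%s scan=%d: %d x %d px, %.3g x %.3g um/px>\n",
              x$participant_id, x$eye, x$visit, x$scan_index,
              x$height_px, x$width_px, x$axial_res_um, x$lateral_res_um))
  invisible(x)
}

#' Per-column retinal boundary positions
#'
#' Holds the internal limiting membrane (ILM) and RPE-base/Bruch's membrane
#' row position for every image column, plus the column range that survived
#' cleaning.  Rows and columns are 0-based: row 0 is the top image row,
#' column 0 the leftmost A-scan.  Rows may be fractional; rasterisation to
#' region maps uses `floor(row)` as the first row of the region below the
#' boundary.
#'
#' @param ilm,rpe numeric vectors of equal length, one row position per
#'   column; `ilm <= rpe` columnwise when `validate = TRUE`.
#' @param valid_start,valid_end inclusive 0-based column range retained after
#'   cleaning (defaults: the full width).
#' @param height_px optional image height for range validation.
#' @param validate enforce the ordering invariants (disable for raw network
#'   predictions, which may transiently violate them).
#' @return an object of class `boundary_set`.
#' @export
boundary_set <- function(ilm, rpe, valid_start = 0L,
                         valid_end = length(ilm) - 1L,
                         height_px = NULL, validate = TRUE) {
  if (length(ilm) != length(rpe))
    stop("`ilm` and `rpe` must have one row per column (equal lengths)")
  w <- length(ilm)
  if (w < 1L) stop("empty boundary set")
  if (valid_start < 0 || valid_start > valid_end || valid_end >= w)
    stop("invalid column range: need 0 <= valid_start <= valid_end < width")
  if (validate) {
    if (anyNA(ilm) || anyNA(rpe)) stop("boundary rows must not be NA")
    if (any(ilm < 0) || any(rpe < ilm))
      stop("boundary invariant violated: need 0 <= ilm <= rpe per column")
    if (!is.null(height_px) && any(rpe > height_px - 1))
      stop("boundary rows exceed image height")
  }
  structure(list(ilm = as.numeric(ilm), rpe = as.numeric(rpe),
                 valid_start = as.integer(valid_start),
                 valid_end = as.integer(valid_end)),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("<boundary_set: %d columns, valid [%d, %d], ilm %.1f-%.1f, rpe %.1f-%.1f>\n",
              length(x$ilm), x$valid_start, x$valid_end,
              min(x$ilm), max(x$ilm), min(x$rpe), max(x$rpe)))
  invisible(x)
}

#' Validate the monotone-column structure of a region map
#'
#' A region map labels each pixel 0 (vitreous + padding), 1 (retina) or
#' 2 (choroid + sclera); along every column the labels must be non-decreasing
#' top to bottom, and classes 0 and 2 must both be present (class 1 may be
#' empty only where the two boundaries coincide).
#'
#' @param regions integer matrix of labels in `{0, 1, 2}`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_region_map <- function(regions) {
  if (!all(regions %in% 0:2)) stop("region labels must be 0, 1 or 2")
  dif <- diff(regions)
  if (any(dif < 0))
    stop("region map violates the monotone-column invariant")
  if (any(regions[1L, ] == 2L) || any(regions[nrow(regions), ] == 0L))
    stop("every column must contain class 0 at the top and class 2 at the bottom")
  invisible(TRUE)
}
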