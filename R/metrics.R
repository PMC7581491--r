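#' Boundary position errors between prediction and truth
#'
#' Comparison is restricted to the truth's valid column range.  MAE is the
#' mean absolute row difference; the mean (signed) error ME is positive when
#' the prediction sits at a larger row index, i.e. lower on the image, than
#' the truth.  Standard deviations of both the absolute and the signed
#' per-column errors are reported.
#'
#' @param pred,truth [boundary_set()]s of equal width.
#' @return a data.frame with one row per boundary (`ilm`, `rpe`) and columns
#'   `mae`, `me`, `sd_ae`, `sd_e`, `n`.
#' @export
boundary_errors <- function(pred, truth) {
  if (length(pred$ilm) != length(truth$ilm))
    stop("prediction and truth widths differ")
  cols <- (truth$valid_start:truth$valid_end) + 1L
  one <- function(p, t) {
    d <- p[cols] - t[cols]
    data.frame(mae = mean(abs(d)), me = mean(d),
               sd_ae = stats::sd(abs(d)), sd_e = stats::sd(d),
               n = length(d))
  }
  out <- rbind(one(pred$ilm, truth$ilm), one(pred$rpe, truth$rpe))
  cbind(boundary = c("ilm", "rpe"), out)
}

#' Average boundary-error tables across folds
#'
#' Arithmetic mean, per boundary and per metric, of the per-fold error tables
#' produced by [boundary_errors()] (the "average" fold strategy, as opposed
#' to voting the maps first and delineating once).
#'
#' @param tables list of data.frames as returned by [boundary_errors()].
#' @return a single averaged data.frame of the same shape.
#' @export
average_fold_errors <- function(tables) {
  if (length(tables) < 1) stop("need at least one fold table")
  out <- tables[[1]]
  num <- vapply(out, is.numeric, logical(1))
  for (cn in names(out)[num])
    out[[cn]] <- rowMeans(vapply(tables, function(t) t[[cn]],
                                 numeric(nrow(out))))
  out
}

#' Hard Dice overlap between two label maps
#'
#' `2|A intersect B| / (|A| + |B|)` per class, in percent, plus the overall
#' mean over classes.  A class empty in both maps is in perfect agreement
#' and scores 100.
#'
#' @param pred,truth integer label matrices of equal shape.
#' @return named numeric vector: one entry per class plus `overall`.
#' @export
dice_overlap <- function(pred, truth, n_classes = 3L) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  per <- vapply(seq_len(n_classes) - 1L, function(cl) {
    a <- pred == cl; b <- truth == cl
    na <- sum(a); nb <- sum(b)
    if (na + nb == 0) return(100)
    200 * sum(a & b) / (na + nb)
  }, numeric(1))
  names(per) <- paste0("class", seq_len(n_classes) - 1L)
  c(per, overall = mean(per))
}

#' En-face retinal thickness map of a volume
#'
#' Thickness at (scan, column) is `(rpe - ilm) * axial_res_um` in microns;
#' en-face positions come from the column pitch and the B-scan spacing,
#' centred on the volume (the phantom's foveal pit sits at the centre; for
#' real data supply `center_mm` to [etdrs_stats()] explicitly).
#'
#' @param boundaries list of per-scan [boundary_set()]s (slices in order).
#' @param axial_res_um,lateral_res_um,scan_spacing_um acquisition geometry.
#' @param clamp treat columns where the boundaries cross (possible in raw
#'   predictions) as zero thickness instead of rejecting.
#' @return an object of class `thickness_map`: matrix `thickness_um`
#'   (scans x columns) plus `x_mm`, `y_mm` cell-centre coordinates.
#' @export
thickness_map <- function(boundaries, axial_res_um, lateral_res_um,
                          scan_spacing_um, clamp = FALSE) {
  th <- t(vapply(boundaries, function(b) (b$rpe - b$ilm) * axial_res_um,
                 numeric(length(boundaries[[1]]$ilm))))
  if (clamp) th <- pmax(th, 0)
  if (any(th < 0)) stop("negative thickness: boundary invariant breached upstream")
  ns <- nrow(th); w <- ncol(th)
  structure(list(
    thickness_um = th,
    x_mm = (seq_len(w) - (w + 1) / 2) * lateral_res_um / 1000,
    y_mm = (seq_len(ns) - (ns + 1) / 2) * scan_spacing_um / 1000,
    cell_mm2 = lateral_res_um * scan_spacing_um / 1e6
  ), class = "thickness_map")
}

#' ETDRS macular grid
#'
#' The standard 9-subfield grid: a central disc of 1 mm diameter, an inner
#' ring to 3 mm and an outer ring to 6 mm, each ring split into superior,
#' nasal, inferior and temporal quadrants along the +-45 degree diagonals.
#' Superior is toward negative `y` (earlier B-scans); nasal/temporal depend
#' on eye laterality: for a right eye (OD) nasal is positive `x`, for a left
#' eye (OS) negative `x`.
#'
#' @param center_mm en-face grid centre (fovea), default the volume centre.
#' @param diameters_mm strictly increasing ring diameters, default 1/3/6 mm.
#' @param laterality `"OD"` or `"OS"`.
#' @return an object of class `etdrs_grid`.
#' @export
etdrs_grid <- function(center_mm = c(0, 0), diameters_mm = c(1, 3, 6),
                       laterality = c("OD", "OS")) {
  if (any(diff(diameters_mm) <= 0)) stop("ring diameters must be increasing")
  structure(list(center_mm = center_mm, diameters_mm = diameters_mm,
                 laterality = match.arg(laterality)),
            class = "etdrs_grid")
}

etdrs_subfield_names <- c("central",
                          "inner_superior", "inner_nasal", "inner_inferior",
                          "inner_temporal",
                          "outer_superior", "outer_nasal", "outer_inferior",
                          "outer_temporal")

# assign each (x, y) cell centre to a subfield index (0 = outside)
etdrs_assign <- function(x, y, grid) {
  dx <- x - grid$center_mm[1]
  dy <- y - grid$center_mm[2]
  r <- sqrt(dx^2 + dy^2)
  rad <- grid$diameters_mm / 2
  ring <- ifelse(r <= rad[1], 1L,
          ifelse(r <= rad[2], 2L, ifelse(r <= rad[3], 3L, 0L)))
  nasal_sign <- if (grid$laterality == "OD") 1 else -1
  quad <- ifelse(abs(dy) >= abs(dx),
                 ifelse(dy <= 0, 1L, 3L),              # superior / inferior
                 ifelse(nasal_sign * dx > 0, 2L, 4L))  # nasal / temporal
  out <- integer(length(x))
  out[ring == 1L] <- 1L
  sel <- ring >= 2L
  out[sel] <- 1L + (ring[sel] - 2L) * 4L + quad[sel]
  out
}

#' ETDRS subfield thickness and volume statistics
#'
#' Cells are assigned to subfields by cell-centre membership (no
#' interpolation between B-scans).  Subfield mean thickness is the average of
#' its samples; subfield volume is the sum of `thickness x cell area`.  The
#' totals aggregate the nine subfields over the full 6 mm disc.
#'
#' @param tmap a [thickness_map()].
#' @param grid an [etdrs_grid()].
#' @return a data.frame (one row per subfield: `mean_um`, `volume_mm3`,
#'   `area_mm2`, `n_cells`) with attributes `total_volume_mm3`,
#'   `total_mean_um` (area-weighted) and the grid.
#' @export
etdrs_stats <- function(tmap, grid = etdrs_grid()) {
  stopifnot(inherits(tmap, "thickness_map"))
  rad_out <- max(grid$diameters_mm) / 2
  if (max(tmap$x_mm) - grid$center_mm[1] < rad_out - 1e-9 ||
      grid$center_mm[1] - min(tmap$x_mm) < rad_out - 1e-9 ||
      max(tmap$y_mm) - grid$center_mm[2] < rad_out - 1e-9 ||
      grid$center_mm[2] - min(tmap$y_mm) < rad_out - 1e-9)
    stop(sprintf(paste0("thickness map (x %.2f..%.2f, y %.2f..%.2f mm) does not ",
                        "cover the %g mm disc around (%.2f, %.2f)"),
                 min(tmap$x_mm), max(tmap$x_mm), min(tmap$y_mm), max(tmap$y_mm),
                 2 * rad_out, grid$center_mm[1], grid$center_mm[2]))
  gx <- rep(tmap$x_mm, each = length(tmap$y_mm))
  gy <- rep(tmap$y_mm, times = length(tmap$x_mm))
  sf <- etdrs_assign(gx, gy, grid)
  th <- as.numeric(tmap$thickness_um)
  out <- data.frame(subfield = etdrs_subfield_names,
                    mean_um = NA_real_, volume_mm3 = NA_real_,
                    area_mm2 = NA_real_, n_cells = NA_integer_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(9)) {
    sel <- sf == k
    out$n_cells[k] <- sum(sel)
    out$mean_um[k] <- mean(th[sel])
    out$volume_mm3[k] <- sum(th[sel]) / 1000 * tmap$cell_mm2
    out$area_mm2[k] <- sum(sel) * tmap$cell_mm2
  }
  attr(out, "total_volume_mm3") <- sum(out$volume_mm3)
  attr(out, "total_mean_um") <- sum(out$mean_um * out$area_mm2) / sum(out$area_mm2)
  attr(out, "grid") <- grid
  out
}

#' Macular volume over a disc
#'
#' Thickness integrated over the central disc (default 6 mm diameter), in
#' cubic millimetres.
#'
#' @param tmap a [thickness_map()].
#' @param center_mm disc centre.
#' @param diameter_mm disc diameter.
#' @return volume in mm^3.
#' @export
macular_volume <- function(tmap, center_mm = c(0, 0), diameter_mm = 6) {
  gx <- rep(tmap$x_mm, each = length(tmap$y_mm))
  gy <- rep(tmap$y_mm, times = length(tmap$x_mm))
  sel <- (gx - center_mm[1])^2 + (gy - center_mm[2])^2 <= (diameter_mm / 2)^2
  sum(as.numeric(tmap$thickness_um)[sel]) / 1000 * tmap$cell_mm2
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements `a` and `b`, reports the mean difference
#' `d = a - b` and the limits of agreement at `mean(d) -+ 1.96 sd(d)`
#' (sample SD, `n - 1` denominator).
#'
#' @param values_a,values_b equal-length paired numeric vectors, `n >= 2`.
#' @return an object of class `bland_altman`: `mean`, `sd`, `lower`, `upper`,
#'   `n`, and the differences.
#' @export
bland_altman <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("paired samples required")
  if (length(values_a) < 2) stop("need n >= 2 pairs")
  d <- values_a - values_b
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean = m, sd = s, lower = m - 1.96 * s, upper = m + 1.96 * s,
                 n = length(d), differences = d,
                 means = (values_a + values_b) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean difference %.4g, limits of agreement [%.4g, %.4g]\n",
              x$n, x$mean, x$lower, x$upper))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "mean of pair", ylab = "difference (a - b)", ...)
  graphics::abline(h = c(x$lower, x$mean, x$upper),
                   lty = c(2, 1, 2), col = c("red", "black", "red"))
  invisible(x)
}
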