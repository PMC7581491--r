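# Dataset I/O: 8-bit grayscale PNG images, CSV boundaries
# (scan_id, column, ilm_row, rpe_row; 0-based columns and rows), JSON
# manifest.  All paths are relative to a dataset root.

#' Write a cohort to disk
#'
#' Layout under `root`: `images/<scan_id>.png` (8-bit grayscale),
#' `boundaries/<scan_id>.csv`, and `manifest.json` carrying the flat scan
#' table plus the seed and a hash of the generating configuration.
#'
#' @param cohort an `oct_cohort`.
#' @param root dataset root directory (created if missing).
#' @return `root`, invisibly.
#' @export
write_cohort <- function(cohort, root) {
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "boundaries"), showWarnings = FALSE)
  man <- cohort_manifest(cohort)
  for (p in cohort$participants)
    for (v in p$volumes)
      for (s in seq_along(v$scans)) {
        id <- sprintf("%s_v%d_s%03d", p$id, v$visit, s - 1L)
        png::writePNG(v$scans[[s]]$pixels / 255,
                      file.path(root, "images", paste0(id, ".png")))
        write_boundaries_csv(v$boundaries[[s]], id,
                             file.path(root, "boundaries", paste0(id, ".csv")))
      }
  meta <- list(seed = cohort$seed, config_hash = config_hash(cohort$config),
               config = unclass(cohort$config),
               volumes_each = cohort$volumes_each,
               scans_per_volume = cohort$scans_per_volume,
               scans = man)
  jsonlite::write_json(meta, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(root)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param root dataset root.
#' @return an `oct_cohort` (ground-truth surfaces are not persisted; the
#'   per-scan boundary sets are).
#' @export
read_cohort <- function(root) {
  meta <- jsonlite::read_json(file.path(root, "manifest.json"),
                              simplifyVector = TRUE)
  man <- meta$scans
  cfg <- do.call(phantom_config, meta$config[names(formals(phantom_config))[
    names(formals(phantom_config)) %in% names(meta$config)]])
  parts <- list()
  for (pid in unique(man$participant_id)) {
    pm <- man[man$participant_id == pid, ]
    vols <- list()
    for (vi in sort(unique(pm$visit))) {
      vm <- pm[pm$visit == vi, ]
      vm <- vm[order(vm$scan_index), ]
      scans <- list(); bsets <- list()
      for (i in seq_len(nrow(vm))) {
        id <- vm$scan_id[i]
        px <- png::readPNG(file.path(root, "images", paste0(id, ".png"))) * 255
        if (length(dim(px)) == 3) px <- px[, , 1]
        scans[[i]] <- bscan(px, lateral_res_um = vm$lateral_res_um[i],
                            axial_res_um = vm$axial_res_um[i],
                            scan_spacing_um = vm$scan_spacing_um[i],
                            participant_id = pid, visit = vi,
                            scan_index = vm$scan_index[i])
        bsets[[i]] <- read_boundaries_csv(
          file.path(root, "boundaries", paste0(id, ".csv")))
      }
      vols[[length(vols) + 1L]] <- list(visit = vi, scans = scans,
                                        boundaries = bsets, surfaces = NULL)
    }
    parts[[length(parts) + 1L]] <- list(
      id = pid, group = pm$group[1], severity = pm$severity[1],
      baseline_volume_mm3 = pm$baseline_volume_mm3[1], volumes = vols)
  }
  structure(list(participants = parts, config = cfg,
                 volumes_each = meta$volumes_each,
                 scans_per_volume = meta$scans_per_volume,
                 seed = meta$seed),
            class = "oct_cohort")
}

#' Write boundaries in the package CSV dialect
#'
#' Columns: `scan_id`, `column` (0-based), `ilm_row`, `rpe_row` (0-based,
#' fractional allowed), plus the valid range repeated per row.
#'
#' @param boundaries a [boundary_set()].
#' @param scan_id identifier recorded in the file.
#' @param path output CSV path.
#' @export
write_boundaries_csv <- function(boundaries, scan_id, path) {
  utils::write.csv(data.frame(
    scan_id = scan_id,
    column = seq_along(boundaries$ilm) - 1L,
    ilm_row = boundaries$ilm, rpe_row = boundaries$rpe,
    valid_start = boundaries$valid_start, valid_end = boundaries$valid_end
  ), path, row.names = FALSE)
}

#' Read boundaries from the package CSV dialect
#' @param path CSV path written by [write_boundaries_csv()].
#' @return a [boundary_set()].
#' @export
read_boundaries_csv <- function(path) {
  d <- utils::read.csv(path)
  d <- d[order(d$column), ]
  boundary_set(d$ilm_row, d$rpe_row, valid_start = d$valid_start[1],
               valid_end = d$valid_end[1], validate = FALSE)
}

#' Save / load probability maps as 32-bit float multi-page TIFF
#'
#' One page per class plane.
#'
#' @param probs `(H, W, C)` or `(H, W, C, 1)` probability array.
#' @param path TIFF path.
#' @export
write_probmap_tiff <- function(probs, path) {
  if (length(dim(probs)) == 4) probs <- array(probs, dim(probs)[1:3])
  pages <- lapply(seq_len(dim(probs)[3]), function(cc) probs[, , cc])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
}

#' @rdname write_probmap_tiff
#' @return `read_probmap_tiff`: the `(H, W, C)` array.
#' @export
read_probmap_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (cc in seq_along(pages)) {
    p <- pages[[cc]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , cc] <- p
  }
  arr
}

#' Save / load a trained model
#'
#' The model is serialised in R's native format with a JSON sidecar
#' recording the architecture, training configuration and seed.
#'
#' @param model an `oct_model`.
#' @param path output path (`.rds`); sidecar written as `<path>.json`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(list(net_cfg = unclass(model$net_cfg),
                            train_cfg = unclass(model$train_cfg)[
                              c("epochs", "batch_size", "contrast_enhance",
                                "augment", "pad_rows", "lr")],
                            seed = model$seed, best_epoch = model$best_epoch,
                            val_dice = model$val_dice,
                            config_hash = config_hash(unclass(model$net_cfg))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Overlay predicted and true boundaries on a scan (QC image)
#'
#' Writes a PNG with the truth as solid lines and predictions as dotted
#' lines (ILM and RPE in different intensities on the red/blue channels).
#'
#' @param scan a [bscan()] or matrix.
#' @param truth,pred [boundary_set()]s (either may be `NULL`).
#' @param path output PNG path.
#' @export
write_overlay_png <- function(scan, truth = NULL, pred = NULL, path) {
  px <- as_pixel_matrix(scan) / 255
  h <- nrow(px); w <- ncol(px)
  rgb <- array(px, c(h, w, 3))
  draw <- function(rows, ch, dotted) {
    cols <- seq_len(w)
    if (dotted) cols <- cols[cols %% 4 < 2]
    r <- pmin(pmax(round(rows[cols]) + 1L, 1L), h)
    for (i in seq_along(cols)) {
      rgb[r[i], cols[i], ] <<- 0
      rgb[r[i], cols[i], ch] <<- 1
    }
  }
  if (!is.null(truth)) { draw(truth$ilm, 3, FALSE); draw(truth$rpe, 1, FALSE) }
  if (!is.null(pred)) { draw(pred$ilm, 3, TRUE); draw(pred$rpe, 1, TRUE) }
  png::writePNG(rgb, path)
  invisible(path)
}
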