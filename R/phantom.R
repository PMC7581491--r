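#' Configuration for the synthetic Stargardt-like OCT phantom
#'
#' The phantom emulates the gross appearance of a macular OCT volume in a
#' Stargardt-like dystrophy: a smooth internal limiting membrane (ILM) with a
#' central foveal pit, an RPE/Bruch's membrane base with low-frequency
#' undulation, variable-severity outer-retinal/RPE atrophy lesions in which
#' the bright RPE band is suppressed and the sub-boundary signal brightened
#' (hypertransmission), hyperreflective flecks above the RPE, multiplicative
#' speckle, and columnar vessel shadows.  It is a geometric test-bed, not a
#' physical reflectivity model.
#'
#' Default geometry is desk scale: 256 columns x 128 rows x 25 slices whose
#' physical extents mimic a clinical macular raster (about 8.8 mm wide,
#' 1.9 mm deep, 6.5 mm of slice coverage so the 6 mm ETDRS zone is covered
#' with under 0.3% disc-area quantisation error).  Full clinical geometry
#' (1536 x 496 x 61 at 5.7 / 3.9 / 119 um) is available by overriding the
#' size and resolution fields.
#'
#' @param height_px,width_px B-scan size in pixels.
#' @param n_scans slices per volume.
#' @param lateral_res_um,axial_res_um,scan_spacing_um physical resolution.
#' @param retina_um baseline total retinal thickness (ILM to RPE base), um.
#' @param pit_depth_um,pit_fwhm_mm foveal pit depth (um) and en-face FWHM (mm).
#' @param rpe_level_frac baseline RPE-base row as a fraction of image height.
#' @param undulation_amp_px,undulation_cycles RPE surface undulation:
#'   amplitude of the fundamental (pixels; harmonics decay as 1/f) and number
#'   of cycles across the scan width.
#' @param n_lesions,lesion_width_px,lesion_extent_mm,lesion_loss_um,severity
#'   atrophy lesions: count, lateral full width (columns), slow-axis full
#'   extent (mm), maximal outer-retinal thinning (um) at severity 1, and
#'   severity in `[0, 1]`.
#' @param n_flecks,fleck_radius_px,fleck_brightness hyperreflective flecks.
#' @param speckle_looks shape ("looks") of the multiplicative Gamma speckle;
#'   0 disables speckle (noise-free phantom).
#' @param n_shadows,shadow_width_px,shadow_attenuation vessel shadows.
#' @param int_vitreous,int_retina,int_rpe,int_choroid,int_sclera region mean
#'   intensities in `[0, 255]`.
#' @param rpe_band_px,choroid_px thickness (rows) of the bright RPE band and
#'   of the choroid band below the RPE base.
#' @param hypertrans_gain intensity added below the RPE base at severity 1
#'   inside lesions (choroidal hypertransmission).
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(height_px = 128L, width_px = 256L, n_scans = 25L,
                           lateral_res_um = 34.4, axial_res_um = 15.1,
                           scan_spacing_um = 260,
                           retina_um = 320, pit_depth_um = 120,
                           pit_fwhm_mm = 1.2, rpe_level_frac = 0.6,
                           undulation_amp_px = 1.5, undulation_cycles = 2L,
                           n_lesions = 1L, lesion_width_px = 60L,
                           lesion_extent_mm = 1.5, lesion_loss_um = 120,
                           severity = 0.6,
                           n_flecks = 6L, fleck_radius_px = 2,
                           fleck_brightness = 60,
                           speckle_looks = 12,
                           n_shadows = 2L, shadow_width_px = 10L,
                           shadow_attenuation = 0.35,
                           int_vitreous = 15, int_retina = 110,
                           int_rpe = 200, int_choroid = 75, int_sclera = 45,
                           rpe_band_px = 3L, choroid_px = 18L,
                           hypertrans_gain = 50) {
  cfg <- as.list(environment())
  for (f in c("height_px", "width_px", "n_scans", "lateral_res_um",
              "axial_res_um", "scan_spacing_um", "retina_um"))
    stopifnot_scalar_num(cfg[[f]], f, lo = 1e-9)
  stopifnot_scalar_num(severity, "severity", 0, 1)
  stopifnot_scalar_num(shadow_attenuation, "shadow_attenuation", 0, 1)
  for (f in c("int_vitreous", "int_retina", "int_rpe", "int_choroid",
              "int_sclera"))
    stopifnot_scalar_num(cfg[[f]], f, 0, 255)
  stopifnot_scalar_num(speckle_looks, "speckle_looks", 0)
  structure(cfg, class = "phantom_config")
}

# en-face coordinates (mm) of columns / scans, centred on the volume
enface_axes <- function(config, n_scans = config$n_scans) {
  list(
    x_mm = (seq_len(config$width_px) - (config$width_px + 1) / 2) *
      config$lateral_res_um / 1000,
    y_mm = (seq_len(n_scans) - (n_scans + 1) / 2) *
      config$scan_spacing_um / 1000
  )
}

#' Generate smooth ground-truth ILM and RPE surfaces for one volume
#'
#' The RPE base is a sum of low-frequency cosines (amplitude decaying as 1/f)
#' around a constant level; the ILM sits above it by a thickness field equal
#' to the baseline thickness minus a Gaussian-profile foveal pit minus the
#' atrophy thinning (raised-cosine lesion windows scaled by severity).
#' Surfaces are fractional pixel rows, 0-based from the image top, with
#' columnwise slope bounded by 1 px/column so that the 3-neighbour boundary
#' graph can follow them exactly.
#'
#' @param config a [phantom_config()].
#' @param rng_seed integer seed; identical seeds give identical surfaces.
#' @param n_scans optional override of `config$n_scans`.
#' @return an object of class `oct_surfaces`: matrices `ilm`, `rpe` and
#'   `atrophy_w` (lesion window in `[0, 1]`), each `n_scans x width_px`, plus
#'   the config and en-face axes.
#' @export
generate_boundary_surfaces <- function(config, rng_seed = 1L,
                                       n_scans = config$n_scans) {
  stopifnot(inherits(config, "phantom_config"))
  ax <- enface_axes(config, n_scans)
  W <- config$width_px
  H <- config$height_px

  with_seed(rng_seed, {
    ncyc <- max(0L, as.integer(config$undulation_cycles))
    phases <- if (ncyc > 0) runif(ncyc, 0, 2 * pi) else numeric(0)
    scan_phase <- runif(1, 0, 2 * pi)
    lesions <- if (config$n_lesions > 0) {
      data.frame(
        x0 = runif(config$n_lesions, 0.25, 0.75) * W * config$lateral_res_um / 1000 -
          W * config$lateral_res_um / 2000,
        y0 = runif(config$n_lesions, -0.3, 0.3) *
          (n_scans * config$scan_spacing_um / 1000)
      )
    } else NULL
  })

  xn <- (seq_len(W) - 1) / (W - 1)                       # 0..1 across width
  und <- rep(0, W)
  if (ncyc > 0)
    for (f in seq_len(ncyc))
      und <- und + (config$undulation_amp_px / f) * cos(2 * pi * f * xn + phases[f])
  scan_mod <- 0.5 * config$undulation_amp_px *
    cos(2 * pi * seq_len(n_scans) / max(n_scans, 2) + scan_phase)

  rpe <- outer(scan_mod, und, `+`) + config$rpe_level_frac * H

  # thickness field (um): baseline - pit - atrophy thinning
  sigma_mm <- config$pit_fwhm_mm / (2 * sqrt(2 * log(2)))
  r2 <- outer(ax$y_mm^2, ax$x_mm^2, `+`)
  thick_um <- config$retina_um - config$pit_depth_um * exp(-r2 / (2 * sigma_mm^2))

  aw <- matrix(0, n_scans, W)
  if (!is.null(lesions)) {
    half_w_mm <- config$lesion_width_px * config$lateral_res_um / 2000
    half_e_mm <- config$lesion_extent_mm / 2
    for (k in seq_len(nrow(lesions))) {
      ux <- abs(ax$x_mm - lesions$x0[k]) / half_w_mm
      uy <- abs(ax$y_mm - lesions$y0[k]) / half_e_mm
      wx <- ifelse(ux < 1, 0.5 * (1 + cos(pi * ux)), 0)
      wy <- ifelse(uy < 1, 0.5 * (1 + cos(pi * uy)), 0)
      aw <- pmax(aw, outer(wy, wx))
    }
  }
  thick_um <- thick_um - config$severity * config$lesion_loss_um * aw

  if (any(thick_um < 0))
    stop("thickness parameters would force ilm > rpe (negative retinal thickness)")
  thick_px <- thick_um / config$axial_res_um
  ilm <- rpe - thick_px

  if (any(ilm < 0) || any(rpe > H - 1))
    stop("surfaces leave the image: adjust rpe_level_frac / retina_um / geometry")
  max_slope <- max(abs(cbind(diff(t(ilm)), diff(t(rpe)))))
  if (max_slope > 1)
    stop(sprintf(paste0("surface slope %.2f px/column exceeds the 1 px/column ",
                        "bound required by the 3-neighbour boundary graph"),
                 max_slope))

  structure(list(ilm = ilm, rpe = rpe, atrophy_w = aw,
                 thickness_um = thick_um,
                 config = config, n_scans = n_scans,
                 x_mm = ax$x_mm, y_mm = ax$y_mm, seed = as.integer(rng_seed)),
            class = "oct_surfaces")
}

#' Render one synthetic B-scan from ground-truth surfaces
#'
#' Paints piecewise-constant region intensities (dark vitreous, retina, a
#' bright RPE band just above the RPE base, choroid, sclera), suppresses the
#' RPE band and brightens the sub-boundary choroid inside atrophy lesions in
#' proportion to `severity x lesion window`, adds Gaussian-profile
#' hyperreflective flecks above the RPE, applies columnar shadow attenuation
#' below the ILM, then multiplicative Gamma speckle, and clips to `[0, 255]`.
#'
#' @param surfaces an `oct_surfaces` object from
#'   [generate_boundary_surfaces()].
#' @param config the [phantom_config()] used for the surfaces.
#' @param rng_seed integer seed for flecks, shadows and speckle.
#' @param slice 1-based slice index into the surfaces object (the resulting
#'   `bscan` records the 0-based `scan_index = slice - 1`).
#' @param participant_id,eye,visit identifiers copied onto the scan.
#' @return a [bscan()].
#' @export
render_bscan <- function(surfaces, config, rng_seed = 1L, slice = 1L,
                         participant_id = NA_character_, eye = "OD",
                         visit = 1L) {
  stopifnot(inherits(surfaces, "oct_surfaces"))
  H <- config$height_px; W <- config$width_px
  ilm_f <- floor(surfaces$ilm[slice, ])
  rpe_f <- floor(surfaces$rpe[slice, ])
  aw <- surfaces$atrophy_w[slice, ]
  supp <- config$severity * aw                      # suppression factor per column

  rmat <- matrix(seq_len(H) - 1, H, W)              # 0-based rows
  ilm_m <- matrix(ilm_f, H, W, byrow = TRUE)
  rpe_m <- matrix(rpe_f, H, W, byrow = TRUE)
  supp_m <- matrix(supp, H, W, byrow = TRUE)

  img <- matrix(config$int_vitreous, H, W)
  img[rmat >= ilm_m & rmat < rpe_m] <- config$int_retina
  band <- rmat >= (rpe_m - config$rpe_band_px) & rmat < rpe_m & rmat >= ilm_m
  img[band] <- (config$int_rpe * (1 - supp_m))[band]
  chor <- rmat >= rpe_m & rmat < (rpe_m + config$choroid_px)
  img[chor] <- (config$int_choroid + config$hypertrans_gain * supp_m)[chor]
  img[rmat >= (rpe_m + config$choroid_px)] <- config$int_sclera

  with_seed(rng_seed, {
    if (config$n_flecks > 0) {
      for (k in seq_len(config$n_flecks)) {
        fc <- sample.int(W, 1)
        lo <- ilm_f[fc] + 2
        hi <- rpe_f[fc] - config$rpe_band_px - 2
        if (hi > lo) {
          fr <- sample(seq(lo, hi), 1)
          rad <- config$fleck_radius_px
          rows <- pmax(1, fr - 3 * rad + 1):pmin(H, fr + 3 * rad + 1)
          cols <- pmax(1, fc - 3 * rad):pmin(W, fc + 3 * rad)
          d2 <- outer((rows - 1 - fr)^2, (cols - fc)^2, `+`)
          img[rows, cols] <- img[rows, cols] +
            config$fleck_brightness * exp(-d2 / (2 * rad^2))
        }
      }
    }
    if (config$n_shadows > 0) {
      for (k in seq_len(config$n_shadows)) {
        c0 <- sample.int(max(1, W - config$shadow_width_px), 1)
        cols <- c0:min(W, c0 + config$shadow_width_px - 1)
        for (cc in cols) {
          rows <- (ilm_f[cc] + 1):H
          img[rows, cc] <- img[rows, cc] * (1 - config$shadow_attenuation)
        }
      }
    }
    if (config$speckle_looks > 0) {
      img <- img * matrix(stats::rgamma(H * W, shape = config$speckle_looks,
                                        rate = config$speckle_looks), H, W)
    }
  })

  img <- pmin(pmax(img, 0), 255)
  bscan(img, lateral_res_um = config$lateral_res_um,
        axial_res_um = config$axial_res_um,
        scan_spacing_um = config$scan_spacing_um,
        participant_id = participant_id, eye = eye, visit = visit,
        scan_index = as.integer(slice) - 1L)
}

# ground-truth macular volume (mm^3) of one surfaces object: thickness
# integrated over the central 6 mm disc when the scan pattern covers it,
# otherwise over the full scanned extent (used only for relative ranking)
surface_macular_volume <- function(surfaces, diameter_mm = 6) {
  cfg <- surfaces$config
  cell_mm2 <- cfg$lateral_res_um * cfg$scan_spacing_um / 1e6
  r2 <- outer(surfaces$y_mm^2, surfaces$x_mm^2, `+`)
  covered <- max(abs(surfaces$x_mm)) >= diameter_mm / 2 &&
    max(abs(surfaces$y_mm)) >= diameter_mm / 2
  sel <- if (covered) r2 <= (diameter_mm / 2)^2 else r2 >= 0
  sum(surfaces$thickness_um[sel]) / 1000 * cell_mm2
}

#' Generate a seeded multi-participant phantom cohort
#'
#' Each participant receives a per-participant atrophy severity and baseline
#' thickness jitter; half the cohort draws mild severities and half severe,
#' so baseline macular volumes straddle the cohort median.  Participants are
#' then labelled `"low"` / `"high"` macular volume by a median split of the
#' baseline (visit 1) ground-truth volume, with ties broken deterministically
#' by participant id order.
#'
#' @param n_participants even number of participants.
#' @param volumes_each volumes (visits) per participant.
#' @param scans_per_volume slices per volume (minimum 3).
#' @param config a [phantom_config()]; per-participant severity overrides the
#'   config's `severity`.
#' @param rng_seed master seed; the whole cohort is reproducible from it.
#' @return an object of class `oct_cohort`: a list of participants (each with
#'   group label, severity, baseline volume and their volumes of rendered
#'   [bscan()]s plus ground-truth [boundary_set()]s and surfaces), the config
#'   and the seed.
#' @export
generate_cohort <- function(n_participants = 12L, volumes_each = 1L,
                            scans_per_volume = config$n_scans,
                            config = phantom_config(), rng_seed = 1L) {
  if (scans_per_volume < 3)
    stop("scans_per_volume must be >= 3 (ETDRS grid needs slice coverage)")
  if (n_participants < 2 || n_participants %% 2 != 0)
    stop("n_participants must be even so low/high volume groups can balance")

  n <- as.integer(n_participants)
  with_seed(rng_seed, {
    sev <- c(stats::runif(n %/% 2, 0.05, 0.25),
             stats::runif(n - n %/% 2, 0.55, 0.85))
    thick_jit <- stats::runif(n, -15, 15)
    seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                               n * volumes_each * (1L + scans_per_volume)),
                    nrow = n)
  })

  ids <- sprintf("P%02d", seq_len(n))
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    pcfg <- config
    pcfg$severity <- sev[i]
    pcfg$retina_um <- config$retina_um + thick_jit[i]
    vols <- vector("list", volumes_each)
    si <- 1L
    for (v in seq_len(volumes_each)) {
      surf <- generate_boundary_surfaces(pcfg, rng_seed = seeds[i, si],
                                         n_scans = scans_per_volume)
      si <- si + 1L
      scans <- vector("list", scans_per_volume)
      bsets <- vector("list", scans_per_volume)
      for (s in seq_len(scans_per_volume)) {
        scans[[s]] <- render_bscan(surf, pcfg, rng_seed = seeds[i, si],
                                   slice = s, participant_id = ids[i],
                                   visit = v)
        si <- si + 1L
        bsets[[s]] <- boundary_set(surf$ilm[s, ], surf$rpe[s, ],
                                   height_px = pcfg$height_px)
      }
      vols[[v]] <- list(visit = v, surfaces = surf, scans = scans,
                        boundaries = bsets)
    }
    participants[[i]] <- list(
      id = ids[i], severity = sev[i],
      baseline_volume_mm3 = surface_macular_volume(vols[[1]]$surfaces),
      volumes = vols
    )
  }

  vol0 <- vapply(participants, `[[`, numeric(1), "baseline_volume_mm3")
  ord <- order(vol0, ids)              # stable: ties broken by participant id
  grp <- character(n)
  grp[ord[seq_len(n %/% 2)]] <- "low"
  grp[ord[(n %/% 2 + 1):n]] <- "high"
  for (i in seq_len(n)) participants[[i]]$group <- grp[i]

  structure(list(participants = participants, config = config,
                 volumes_each = as.integer(volumes_each),
                 scans_per_volume = as.integer(scans_per_volume),
                 seed = as.integer(rng_seed)),
            class = "oct_cohort")
}

#' @export
print.oct_cohort <- function(x, ...) {
  grp <- vapply(x$participants, `[[`, character(1), "group")
  cat(sprintf("<oct_cohort: %d participants (%d low / %d high), %d volume(s) each, %d scans/volume, seed %d>\n",
              length(x$participants), sum(grp == "low"), sum(grp == "high"),
              x$volumes_each, x$scans_per_volume, x$seed))
  invisible(x)
}

#' Cohort manifest
#'
#' Flat summary of a cohort: one row per scan with participant, group, visit,
#' scan index and geometry.  This is what is written as `manifest.json` by
#' [write_cohort()].
#'
#' @param cohort an `oct_cohort`.
#' @return a data.frame.
#' @export
cohort_manifest <- function(cohort) {
  rows <- list()
  for (p in cohort$participants)
    for (v in p$volumes)
      for (s in seq_along(v$scans)) {
        sc <- v$scans[[s]]
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = p$id, group = p$group, visit = v$visit,
          scan_index = sc$scan_index,
          scan_id = sprintf("%s_v%d_s%03d", p$id, v$visit, sc$scan_index),
          height_px = sc$height_px, width_px = sc$width_px,
          lateral_res_um = sc$lateral_res_um, axial_res_um = sc$axial_res_um,
          scan_spacing_um = sc$scan_spacing_um,
          baseline_volume_mm3 = p$baseline_volume_mm3,
          severity = p$severity,
          stringsAsFactors = FALSE
        )
      }
  do.call(rbind, rows)
}
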