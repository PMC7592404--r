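# Synthetic apical-lung phantoms. The phantom stands in for the cylindrical
# VOI neighbourhood of a planning CT: healthy parenchyma is a spatially
# correlated mid-density field (the vessel/airway/alveoli mix) with bright
# tubular vessels, and emphysema is modelled as low-density, internally
# homogeneous spherical bullae overwriting tissue until a target volume
# fraction (the severity) is reached. Grey levels follow the offset
# stored-value convention of the study scanner (healthy apical parenchyma
# ~200-250), not Hounsfield units.

#' Phantom generation parameters
#'
#' Defaults emulate the study's acquisition geometry (1 x 1 mm in-plane,
#' 2.5 mm slices) and give a healthy-tissue density scale consistent with
#' the offset grey levels the study reports. `severity` is the emphysema
#' burden: the target bulla volume fraction in `[0, 1]`.
#'
#' @param shape integer length-3 grid size (rows, columns, slices).
#' @param spacing voxel spacing in mm.
#' @param severity bulla volume fraction in `[0, 1]`.
#' @param base_density mean healthy-tissue grey level.
#' @param texture_sd grey-level spread of healthy tissue (after smoothing).
#' @param smooth_mm Gaussian correlation length (mm) of the parenchymal field.
#' @param vessel_density expected tubular structures per cm^3.
#' @param vessel_brightness grey-level increment inside vessels.
#' @param bulla_value mean grey level inside bullae (near-air; must be below
#'   `base_density`).
#' @param bulla_radius_mm length-2 range of bulla radii (mm).
#' @param bulla_interior_sd grey-level noise inside bullae; must be well
#'   below `texture_sd` (bullae are internally homogeneous).
#' @param noise_sd additive acquisition noise (grey levels).
#' @param seed RNG seed; the same parameters and seed reproduce the volume
#'   bit for bit.
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(48L, 48L, 14L), spacing = c(1, 1, 2.5),
                           severity = 0, base_density = 220, texture_sd = 60,
                           smooth_mm = 1.5, vessel_density = 0.2,
                           vessel_brightness = 250, bulla_value = 30,
                           bulla_radius_mm = c(2, 6), bulla_interior_sd = 8,
                           noise_sd = 12, seed = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L),
            length(spacing) == 3L, all(spacing > 0),
            length(bulla_radius_mm) == 2L,
            bulla_radius_mm[1] > 0, diff(bulla_radius_mm) >= 0)
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  if (bulla_interior_sd >= texture_sd)
    stop("bulla_interior_sd must be below texture_sd (bullae are homogeneous)")
  if (bulla_value >= base_density)
    stop("bulla_value must be below base_density")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 severity = severity, base_density = base_density,
                 texture_sd = texture_sd, smooth_mm = smooth_mm,
                 vessel_density = vessel_density,
                 vessel_brightness = vessel_brightness,
                 bulla_value = bulla_value,
                 bulla_radius_mm = as.numeric(bulla_radius_mm),
                 bulla_interior_sd = bulla_interior_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_params")
}

# separable Gaussian smoothing of a 3-D array; sigma per axis in voxels
gauss_smooth_3d <- function(a, sigma_vox) {
  conv_axis1 <- function(m, k) {
    hw <- (length(k) - 1L) / 2L
    if (hw == 0L) return(m)
    mp <- rbind(m[rep(1L, hw), , drop = FALSE], m,
                m[rep(nrow(m), hw), , drop = FALSE])
    out <- stats::filter(mp, k, sides = 2)
    matrix(out[(hw + 1L):(hw + nrow(m)), ], nrow(m), ncol(m))
  }
  kern <- function(s) {
    if (s <= 1e-8) return(1)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k / sum(k)
  }
  d <- dim(a)
  a <- array(conv_axis1(matrix(a, d[1]), kern(sigma_vox[1])), d)
  a <- aperm(array(conv_axis1(matrix(aperm(a, c(2, 1, 3)), d[2]),
                              kern(sigma_vox[2])), d[c(2, 1, 3)]), c(2, 1, 3))
  a <- aperm(array(conv_axis1(matrix(aperm(a, c(3, 1, 2)), d[3]),
                              kern(sigma_vox[3])), d[c(3, 1, 2)]), c(2, 3, 1))
  a
}

#' Generate one synthetic apical-lung phantom
#'
#' Healthy background: Gaussian-smoothed white noise rescaled to
#' (`base_density`, `texture_sd`), plus bright tubular vessel segments placed
#' at `vessel_density` per cm^3. Emphysema: spheres with radii drawn from
#' `bulla_radius_mm` are placed uniformly at random, overwriting tissue with
#' `bulla_value + N(0, bulla_interior_sd)`, until the bulla volume fraction
#' reaches the severity. Additive acquisition noise `N(0, noise_sd)` is
#' applied last.
#'
#' @param params a [phantom_params].
#' @return list with `volume` (a [ct_volume]), `bulla_mask` (logical
#'   ground-truth array) and `params`.
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  d <- params$shape; sp <- params$spacing
  nvox <- prod(d)
  field <- array(stats::rnorm(nvox), d)
  field <- gauss_smooth_3d(field, params$smooth_mm / sp)
  field <- (field - mean(field)) / stats::sd(field)
  vol <- params$base_density + params$texture_sd * field

  # vessels: random line segments, voxels within the vessel radius brightened
  extent <- d * sp
  vol_cm3 <- prod(extent) / 1000
  n_vessels <- stats::rpois(1, params$vessel_density * vol_cm3)
  if (n_vessels > 0) {
    for (v in seq_len(n_vessels)) {
      p0 <- stats::runif(3) * extent
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      rad <- stats::runif(1, 0.8, 1.5)
      L <- sqrt(sum(extent^2))
      tt <- seq(-L, L, by = min(sp) / 2)
      pts <- cbind(p0[1] + tt * dir[1], p0[2] + tt * dir[2], p0[3] + tt * dir[3])
      keep <- pts[, 1] >= 0 & pts[, 1] <= extent[1] &
        pts[, 2] >= 0 & pts[, 2] <= extent[2] &
        pts[, 3] >= 0 & pts[, 3] <= extent[3]
      pts <- pts[keep, , drop = FALSE]
      if (!nrow(pts)) next
      ij <- cbind(pmin(pmax(round(pts[, 1] / sp[1] + 0.5), 1), d[1]),
                  pmin(pmax(round(pts[, 2] / sp[2] + 0.5), 1), d[2]),
                  pmin(pmax(round(pts[, 3] / sp[3] + 0.5), 1), d[3]))
      ij <- ij[!duplicated(ij), , drop = FALSE]
      vmask <- array(FALSE, d); vmask[ij] <- TRUE
      if (rad > min(sp)) {          # thicken in-plane for wide vessels
        sh <- vmask
        sh[c(2:d[1], d[1]), , ] <- sh[c(2:d[1], d[1]), , ] | vmask
        sh[, c(2:d[2], d[2]), ] <- sh[, c(2:d[2], d[2]), ] | vmask
        vmask <- sh
      }
      vol[vmask] <- vol[vmask] + params$vessel_brightness
    }
  }

  # bullae: accumulate random spheres until the volume fraction hits severity
  bmask <- array(FALSE, d)
  if (params$severity > 0) {
    cx <- (seq_len(d[1]) - 0.5) * sp[1]
    cy <- (seq_len(d[2]) - 0.5) * sp[2]
    cz <- (seq_len(d[3]) - 0.5) * sp[3]
    max_tries <- 5000L
    tries <- 0L
    while (mean(bmask) < params$severity) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("bulla volume fraction ", params$severity,
             " unreachable in a ", paste(d, collapse = "x"), " grid")
      ctr <- stats::runif(3) * extent
      rad <- stats::runif(1, params$bulla_radius_mm[1], params$bulla_radius_mm[2])
      i1 <- which(abs(cx - ctr[1]) <= rad)
      i2 <- which(abs(cy - ctr[2]) <= rad)
      i3 <- which(abs(cz - ctr[3]) <= rad)
      if (!length(i1) || !length(i2) || !length(i3)) next
      dx2 <- (cx[i1] - ctr[1])^2
      dy2 <- (cy[i2] - ctr[2])^2
      dz2 <- (cz[i3] - ctr[3])^2
      sph <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rad^2
      bmask[i1, i2, i3] <- bmask[i1, i2, i3, drop = FALSE] | sph
    }
    nb <- sum(bmask)
    vol[bmask] <- params$bulla_value +
      stats::rnorm(nb, sd = params$bulla_interior_sd)
  }

  vol <- vol + stats::rnorm(nvox, sd = params$noise_sd)
  list(volume = ct_volume(vol, spacing = sp), bulla_mask = bmask,
       params = params)
}

#' Default lung-function mapping parameters
#'
#' Linear decline of FEV1 and TLCO %-predicted with emphysema severity,
#' with independent Gaussian noise, calibrated so that the default cohort's
#' group means land near the study's (fit about 85/74, unfit about 53/43).
#'
#' @param fev1_intercept,fev1_slope FEV1 = intercept - slope * severity.
#' @param tlco_intercept,tlco_slope TLCO likewise.
#' @param noise_sd per-patient noise (percent of predicted).
#' @export
lungfunction_mapping <- function(fev1_intercept = 95, fev1_slope = 90,
                                 tlco_intercept = 80, tlco_slope = 90,
                                 noise_sd = 8) {
  list(fev1_intercept = fev1_intercept, fev1_slope = fev1_slope,
       tlco_intercept = tlco_intercept, tlco_slope = tlco_slope,
       noise_sd = noise_sd)
}

#' Map emphysema severity to lung-function values
#'
#' Monotone decreasing in severity in expectation; values are clamped to the
#' physiological range 10-130% of predicted.
#'
#' @param s severity in `[0, 1]` (vectorised).
#' @param mapping a [lungfunction_mapping].
#' @param seed optional RNG seed.
#' @return data.frame `fev1_pct`, `tlco_pct`.
#' @export
severity_to_lungfunction <- function(s, mapping = lungfunction_mapping(),
                                     seed = NULL) {
  if (any(s < 0 | s > 1)) stop("severity must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(s)
  clamp <- function(x) pmin(pmax(x, 10), 130)
  data.frame(
    fev1_pct = clamp(mapping$fev1_intercept - mapping$fev1_slope * s +
                       stats::rnorm(n, sd = mapping$noise_sd)),
    tlco_pct = clamp(mapping$tlco_intercept - mapping$tlco_slope * s +
                       stats::rnorm(n, sd = mapping$noise_sd)))
}

#' Cohort simulation parameters
#'
#' Defaults follow the study composition: 29 fit patients (low severity,
#' `Beta(2, 18)`) and 32 unfit patients (moderate-to-severe, `Beta(18, 22)`).
#' The first fit patient is generated at severity 0 and flagged as the
#' reference for quantisation-scheme derivation (the "fit non-smoker").
#'
#' @param n_fit,n_unfit group sizes (>= 2).
#' @param fit_severity,unfit_severity length-2 Beta shape parameters of the
#'   per-group severity distributions.
#' @param mapping a [lungfunction_mapping].
#' @param phantom a [phantom_params] used as the template for every patient
#'   (severity and seed are overridden per patient).
#' @param seed master seed for the cohort.
#' @export
cohort_sim_params <- function(n_fit = 29L, n_unfit = 32L,
                              fit_severity = c(2, 18),
                              unfit_severity = c(18, 22),
                              mapping = lungfunction_mapping(),
                              phantom = phantom_params(),
                              seed = 1L) {
  stopifnot(n_fit >= 2L, n_unfit >= 2L, inherits(phantom, "phantom_params"))
  structure(list(n_fit = as.integer(n_fit), n_unfit = as.integer(n_unfit),
                 fit_severity = fit_severity, unfit_severity = unfit_severity,
                 mapping = mapping, phantom = phantom, seed = seed),
            class = "cohort_sim_params")
}

#' Generate a synthetic cohort
#'
#' Draws a severity per patient from the group's Beta distribution, maps it
#' to lung function and generates the phantom volume. All randomness flows
#' from the master seed; per-patient phantom seeds are drawn up front so the
#' cohort is reproducible patient by patient.
#'
#' @param params a [cohort_sim_params].
#' @return list with `volumes` (named list of [ct_volume]), `bulla_masks`,
#'   `lung_function` (data.frame), `truth` (data.frame with intended group,
#'   severity and per-patient seed), `reference_id` (the severity-0 fit
#'   patient whose VOI fixes the quantisation edges) and `cylinder` (a
#'   [cylinder_spec] centred in the phantom).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(params$seed)
  n <- params$n_fit + params$n_unfit
  group <- c(rep("fit", params$n_fit), rep("unfit", params$n_unfit))
  sev <- c(stats::rbeta(params$n_fit, params$fit_severity[1], params$fit_severity[2]),
           stats::rbeta(params$n_unfit, params$unfit_severity[1], params$unfit_severity[2]))
  sev[1] <- 0                               # reference patient: pristine lung
  ids <- sprintf("P%02d", seq_len(n))
  lf_vals <- severity_to_lungfunction(sev, params$mapping)  # uses stream
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  volumes <- vector("list", n); names(volumes) <- ids
  bulla_masks <- vector("list", n); names(bulla_masks) <- ids
  for (i in seq_len(n)) {
    pp <- params$phantom
    pp$severity <- sev[i]
    pp$seed <- seeds[i]
    ph <- generate_phantom(pp)
    volumes[[i]] <- ph$volume
    bulla_masks[[i]] <- ph$bulla_mask
  }
  lf <- data.frame(patient_id = ids,
                   fev1_pct = lf_vals$fev1_pct,
                   tlco_pct = lf_vals$tlco_pct,
                   stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = ids, group = group, severity = sev,
                      seed = seeds, stringsAsFactors = FALSE)
  list(volumes = volumes, bulla_masks = bulla_masks, lung_function = lf,
       truth = truth, reference_id = ids[1],
       cylinder = default_cylinder_spec(params$phantom))
}

#' Cylinder placement for a phantom
#'
#' Centres the study cylinder in-plane and starts it at the second slice
#' (one guard slice at the apex), with `n_slices` chosen to fit.
#'
#' @param phantom a [phantom_params] (or a [ct_volume]).
#' @param diameter_mm,n_slices cylinder geometry; study defaults.
#' @export
default_cylinder_spec <- function(phantom, diameter_mm = 40, n_slices = 10L) {
  if (inherits(phantom, "ct_volume")) {
    d <- dim(phantom$voxels); sp <- phantom$spacing
  } else {
    d <- phantom$shape; sp <- phantom$spacing
  }
  cylinder_spec(center_xy = (d[1:2] - 1) * sp[1:2] / 2,
                top_slice = 2L, diameter_mm = diameter_mm,
                n_slices = n_slices,
                expected_slice_thickness_mm = sp[3])
}

#' Write a simulated cohort to disk
#'
#' Writes per-patient NIfTI volumes (`<id>.nii.gz`) and ground-truth bulla
#' masks (`<id>_bullae.nii.gz`), `lung_function.csv`, and `truth.json`
#' (intended labels, severities, per-patient seeds, reference id).
#'
#' @param cohort as returned by [generate_cohort].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$volumes)) {
    write_volume(cohort$volumes[[id]], file.path(dir, paste0(id, ".nii.gz")))
    bm <- ct_volume(array(as.integer(cohort$bulla_masks[[id]]),
                          dim(cohort$volumes[[id]]$voxels)),
                    spacing = cohort$volumes[[id]]$spacing)
    write_volume(bm, file.path(dir, paste0(id, "_bullae.nii.gz")))
  }
  write_lung_function(cohort$lung_function, file.path(dir, "lung_function.csv"))
  jsonlite::write_json(list(reference_id = cohort$reference_id,
                            truth = cohort$truth,
                            cylinder = unclass(cohort$cylinder)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
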