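#' Specification of the apical cylindrical VOI
#'
#' The study geometry: a 4 cm-diameter circle drawn on 10 consecutive
#' 2.5 mm slices of the lung apex contralateral to the tumour, giving a
#' right circular cylinder 4 cm across and 2.5 cm tall. The cylinder axis
#' is perpendicular to the slice plane; placement (in-plane centre and most
#' apical slice) is supplied explicitly -- apex localisation is manual or,
#' for phantoms, comes from the generator.
#'
#' @param center_xy numeric length-2, in-plane centre (mm) in the volume's
#'   physical coordinates (row axis first).
#' @param top_slice integer, 1-based index of the most apical slice included.
#' @param diameter_mm cylinder diameter in mm; the study used 40.
#' @param n_slices number of consecutive slices; the study used 10.
#' @param expected_slice_thickness_mm nominal slice thickness (mm); if the
#'   volume's actual `dz` differs, [make_cylinder_mask] warns and keeps the
#'   `n_slices`-slices semantics.
#' @return An object of class `cylinder_spec`.
#' @export
cylinder_spec <- function(center_xy, top_slice, diameter_mm = 40,
                          n_slices = 10L, expected_slice_thickness_mm = 2.5) {
  center_xy <- as.numeric(center_xy)
  if (length(center_xy) != 2L || any(!is.finite(center_xy)))
    stop("center_xy must be 2 finite mm coordinates")
  if (!is.finite(diameter_mm) || diameter_mm <= 0)
    stop("diameter_mm must be positive")
  n_slices <- as.integer(n_slices)
  top_slice <- as.integer(top_slice)
  if (is.na(n_slices) || n_slices < 1L) stop("n_slices must be >= 1")
  if (is.na(top_slice) || top_slice < 1L) stop("top_slice must be >= 1")
  structure(list(center_xy = center_xy, top_slice = top_slice,
                 diameter_mm = diameter_mm, n_slices = n_slices,
                 expected_slice_thickness_mm = expected_slice_thickness_mm),
            class = "cylinder_spec")
}

#' Build the cylindrical VOI mask over a volume
#'
#' A voxel belongs to the mask iff its in-plane centre lies strictly within
#' `diameter_mm / 2` of the cylinder centre and its slice index lies in
#' `[top_slice, top_slice + n_slices - 1]`. The strict-interior rule on voxel
#' centres makes the mask reproducible and resolution-independent.
#'
#' @param volume a [ct_volume].
#' @param spec a [cylinder_spec].
#' @return An object of class `roi_mask`: logical array `mask` congruent with
#'   the volume plus the volume's shape and spacing.
#' @export
make_cylinder_mask <- function(volume, spec) {
  stopifnot(inherits(volume, "ct_volume"), inherits(spec, "cylinder_spec"))
  d <- dim(volume$voxels)
  r <- spec$diameter_mm / 2
  cc <- voxel_centres(volume)
  lo_slice <- spec$top_slice
  hi_slice <- spec$top_slice + spec$n_slices - 1L
  if (hi_slice > d[3])
    stop("cylinder extends beyond the last slice (needs slices ",
         lo_slice, "..", hi_slice, ", volume has ", d[3], ")")
  # physical extent check: the circle must lie inside the in-plane grid
  half <- volume$spacing[1:2] / 2
  if (spec$center_xy[1] - r < cc$x[1] - half[1] ||
      spec$center_xy[1] + r > cc$x[d[1]] + half[1] ||
      spec$center_xy[2] - r < cc$y[1] - half[2] ||
      spec$center_xy[2] + r > cc$y[d[2]] + half[2])
    stop("cylinder extends outside the in-plane volume extent")
  if (abs(volume$spacing[3] - spec$expected_slice_thickness_mm) > 1e-6)
    warning(sprintf(
      "slice thickness %.3g mm differs from expected %.3g mm; keeping %d slices (height %.3g mm)",
      volume$spacing[3], spec$expected_slice_thickness_mm, spec$n_slices,
      spec$n_slices * volume$spacing[3]))
  circ <- outer((cc$x - spec$center_xy[1])^2,
                (cc$y - spec$center_xy[2])^2, "+") < r^2
  mask <- array(FALSE, d)
  mask[, , lo_slice:hi_slice] <- circ
  if (!any(mask))
    stop("cylinder mask contains no voxels (diameter below voxel size?)")
  structure(list(mask = mask, shape = d, spacing = volume$spacing),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s voxels, %d in mask\n",
              paste(x$shape, collapse = " x "), sum(x$mask)), sep = "")
  invisible(x)
}

#' Extract masked voxel values with their coordinates
#'
#' Returns the grey levels at every true mask voxel together with the voxel's
#' integer indices, in deterministic column-major order (row index varies
#' fastest, then column, then slice).
#'
#' @param volume a [ct_volume].
#' @param mask an [roi_mask] congruent with the volume.
#' @return data.frame with integer columns `i`, `j`, `k` and numeric `value`;
#'   one row per in-mask voxel.
#' @export
extract_roi <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$voxels), mask$shape))
    stop("mask shape ", paste(mask$shape, collapse = "x"),
         " does not match volume shape ",
         paste(dim(volume$voxels), collapse = "x"))
  idx <- which(mask$mask)
  ai <- arrayInd(idx, mask$shape)
  data.frame(i = ai[, 1], j = ai[, 2], k = ai[, 3],
             value = volume$voxels[idx])
}

#' Write an ROI mask as a 0/1 NIfTI volume
#' @param mask an [roi_mask].
#' @param path output NIfTI path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$mask), mask$shape))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
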