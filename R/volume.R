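#' CT volume container
#'
#' A `ct_volume` holds a 3-D grid of grey-level values together with its
#' physical voxel spacing and origin. Grey levels are kept in whatever units
#' the source carries (scanner-native stored values after any slope/intercept
#' rescaling); absolute density values are therefore convention-dependent and
#' the pipeline never assumes Hounsfield calibration.
#'
#' Axis convention: arrays are indexed `[row, column, slice]`; the slice
#' index (third dimension) increases inferior to superior, so the lung apex
#' sits at low slice indices near the top of the imaged stack's superior end.
#' This convention is fixed, not configurable.
#'
#' @param voxels numeric 3-D array of grey levels.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm; all
#'   components must be positive.
#' @param origin numeric length-3, physical position (mm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L))
    stop("voxels must be a 3-D array with each dimension >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  grey levels: [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Physical in-plane coordinates of voxel centres
#'
#' Voxel centre `[i, j, k]` is at `origin + (c(i, j, k) - 1) * spacing`.
#' @param volume a [ct_volume].
#' @return list with numeric vectors `x` (rows), `y` (columns), `z` (slices).
#' @keywords internal
voxel_centres <- function(volume) {
  d <- dim(volume$voxels)
  list(x = volume$origin[1] + (seq_len(d[1]) - 1) * volume$spacing[1],
       y = volume$origin[2] + (seq_len(d[2]) - 1) * volume$spacing[2],
       z = volume$origin[3] + (seq_len(d[3]) - 1) * volume$spacing[3])
}

#' Read a CT volume from a NIfTI file
#'
#' Reads a 3-D NIfTI image (`.nii` / `.nii.gz`). Any `scl_slope` /
#' `scl_inter` rescaling stored in the header is applied by the reader, so
#' the returned grey levels are the image's intended values; no further
#' rescaling is done. Directories (DICOM series) are rejected: convert a
#' series to NIfTI first.
#'
#' @param path path to a NIfTI file.
#' @return A [ct_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("volume file not found: ", path)
  if (dir.exists(path))
    stop("'", path, "' is a directory; DICOM series input is not supported, ",
         "convert the series to a NIfTI file")
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("image in '", path, "' is not 3-D (found ", length(dim(a)),
         " dimensions); a single 3-D volume is required")
  sp <- RNifti::pixdim(img)[1:3]
  ct_volume(a, spacing = sp, origin = c(0, 0, 0))
}

#' Write a CT volume to a NIfTI file
#'
#' @param volume a [ct_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Ordered series of breathing-phase volumes
#'
#' Wraps the phases of a 4-D CT acquisition (typically 10 breathing phases).
#' All phases must share shape and spacing.
#'
#' @param phases list of [ct_volume] objects.
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(phases) {
  if (!is.list(phases) || length(phases) < 1L)
    stop("phases must be a non-empty list of ct_volume objects")
  if (!all(vapply(phases, inherits, logical(1), "ct_volume")))
    stop("every phase must be a ct_volume")
  d0 <- dim(phases[[1]]$voxels); s0 <- phases[[1]]$spacing
  for (p in phases[-1]) {
    if (!identical(dim(p$voxels), d0))
      stop("phase shapes differ: ", paste(d0, collapse = "x"), " vs ",
           paste(dim(p$voxels), collapse = "x"))
    if (any(abs(p$spacing - s0) > 1e-9))
      stop("phase spacings differ")
  }
  structure(list(phases = phases), class = "phase_series")
}

#' Collapse a phase series into an average-intensity (AVIP) volume
#'
#' The average intensity projection is the voxel-wise arithmetic mean across
#' breathing phases; apical parenchyma moves little with respiration, so the
#' mean is a pragmatic single-volume summary of a 4-D acquisition. The
#' pipeline itself needs only one 3-D volume, so this step is optional
#' pre-processing.
#'
#' @param series a [phase_series].
#' @return A [ct_volume] with the mean grey level at every voxel; spacing and
#'   origin are copied from the first phase.
#' @export
average_phases <- function(series) {
  stopifnot(inherits(series, "phase_series"))
  ph <- series$phases
  acc <- ph[[1]]$voxels
  if (length(ph) > 1L) for (p in ph[-1]) acc <- acc + p$voxels
  ct_volume(acc / length(ph), spacing = ph[[1]]$spacing,
            origin = ph[[1]]$origin)
}

#' Read a per-patient lung-function table
#'
#' Expects a CSV with header columns `patient_id`, `fev1_pct`, `tlco_pct`
#' (forced expiratory volume in 1 s and carbon-monoxide transfer factor,
#' both as percent of the predicted value for age/height/gender).
#'
#' @param path CSV path.
#' @return data.frame with character `patient_id` and numeric `fev1_pct`,
#'   `tlco_pct`; patient ids are unique and percentages strictly positive.
#' @export
read_lung_function <- function(path) {
  if (!file.exists(path)) stop("lung-function file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_lung_function(df)
}

#' @rdname read_lung_function
#' @param lf a lung-function data.frame as returned by [read_lung_function].
#' @export
write_lung_function <- function(lf, path) {
  validate_lung_function(lf)
  utils::write.csv(lf[, c("patient_id", "fev1_pct", "tlco_pct")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a lung-function table
#' @keywords internal
validate_lung_function <- function(df) {
  need <- c("patient_id", "fev1_pct", "tlco_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("lung-function table missing column(s): ", paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  df$fev1_pct <- as.numeric(df$fev1_pct)
  df$tlco_pct <- as.numeric(df$tlco_pct)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in lung-function table: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  bad <- !is.finite(df$fev1_pct) | !is.finite(df$tlco_pct) |
    df$fev1_pct <= 0 | df$tlco_pct <= 0
  if (any(bad))
    stop("non-positive or missing lung-function percentage for patient(s): ",
         paste(df$patient_id[bad], collapse = ", "))
  df[, need]
}
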