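# End-to-end orchestration: volumes + lung function in, feature table and
# fit/unfit comparison out. Stage order is fixed: read -> (optional AVIP
# upstream) -> cylinder mask -> ROI extraction -> derive quantisation edges
# from the reference patient (once) -> quantise every patient with those
# edges -> entropy maps -> feature records -> fitness labels -> cohort
# comparison and lung-function correlations. Everything after the inputs is
# deterministic, so a rerun with the same config reproduces the output files
# byte for byte.

#' Pipeline configuration
#'
#' @param input either a cohort list as returned by [generate_cohort], or a
#'   directory written by [write_cohort] (per-patient NIfTI volumes,
#'   `lung_function.csv`, `truth.json`).
#' @param output_dir directory for result files (created if missing).
#' @param cylinder a [cylinder_spec]; `NULL` uses the cohort's own placement
#'   (from the generator or `truth.json`).
#' @param reference_id patient whose VOI fixes the quantisation edges;
#'   `NULL` uses the cohort's flagged reference.
#' @param n_levels quantisation levels (default 16).
#' @param density_max,entropy_max low-density low-entropy subregion
#'   thresholds; `NULL` for the defaults documented in
#'   [build_feature_record].
#' @param threshold_pct fitness threshold, percent of predicted (default 50).
#' @param write_maps write each patient's entropy map and the VOI mask as
#'   NIfTI.
#' @param write_figures write per-patient density-entropy histogram and
#'   entropy-slice PNGs via [render_maps].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output_dir, cylinder = NULL,
                            reference_id = NULL, n_levels = 16L,
                            density_max = NULL, entropy_max = NULL,
                            threshold_pct = 50, write_maps = FALSE,
                            write_figures = FALSE) {
  structure(list(input = input, output_dir = output_dir, cylinder = cylinder,
                 reference_id = reference_id, n_levels = as.integer(n_levels),
                 density_max = density_max, entropy_max = entropy_max,
                 threshold_pct = threshold_pct, write_maps = write_maps,
                 write_figures = write_figures),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config] arguments (`input`,
#' `output_dir`, `reference_id`, `n_levels`, `density_max`, `entropy_max`,
#' `threshold_pct`, `write_maps`, `write_figures`); an optional `cylinder`
#' section holds the [cylinder_spec] fields (`center_xy`, `top_slice`,
#' `diameter_mm`, `n_slices`, `expected_slice_thickness_mm`). Relative input
#' paths are resolved against the config file's directory.
#'
#' @param path YAML file.
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  for (k in c("input", "output_dir"))
    if (is.null(y[[k]])) stop("config is missing required key '", k, "'")
  resolve <- function(p) {
    if (grepl("^(/|~)", p)) p else file.path(dirname(path), p)
  }
  cyl <- NULL
  if (!is.null(y$cylinder))
    cyl <- cylinder_spec(
      unlist(y$cylinder$center_xy), y$cylinder$top_slice,
      y$cylinder$diameter_mm %||% 40, y$cylinder$n_slices %||% 10L,
      y$cylinder$expected_slice_thickness_mm %||% 2.5)
  pipeline_config(resolve(y$input), resolve(y$output_dir), cylinder = cyl,
                  reference_id = y$reference_id,
                  n_levels = y$n_levels %||% 16L,
                  density_max = y$density_max, entropy_max = y$entropy_max,
                  threshold_pct = y$threshold_pct %||% 50,
                  write_maps = isTRUE(y$write_maps),
                  write_figures = isTRUE(y$write_figures))
}

load_cohort_dir <- function(dir) {
  lf_path <- file.path(dir, "lung_function.csv")
  if (!file.exists(lf_path)) stop("no lung_function.csv in ", dir)
  lf <- read_lung_function(lf_path)
  truth_path <- file.path(dir, "truth.json")
  reference_id <- NULL; cyl <- NULL
  if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    reference_id <- tr$reference_id
    if (!is.null(tr$cylinder))
      cyl <- cylinder_spec(tr$cylinder$center_xy, tr$cylinder$top_slice,
                           tr$cylinder$diameter_mm, tr$cylinder$n_slices,
                           tr$cylinder$expected_slice_thickness_mm)
  }
  volumes <- lapply(lf$patient_id, function(id) {
    p <- file.path(dir, paste0(id, ".nii.gz"))
    if (!file.exists(p)) p <- file.path(dir, paste0(id, ".nii"))
    read_volume(p)
  })
  names(volumes) <- lf$patient_id
  list(volumes = volumes, lung_function = lf, reference_id = reference_id,
       cylinder = cyl)
}

#' Run the full analysis pipeline
#'
#' Executes every stage for every patient and writes `features.csv`,
#' `comparison.csv`, `correlations.csv`, `scheme.json` and `manifest.json`
#' to the output directory. A stage failure aborts with the patient id and
#' stage name. The quantisation scheme is derived exactly once, from the
#' reference patient, and applied unchanged to all patients; the manifest
#' records its edges.
#'
#' @param config a [pipeline_config].
#' @return list with `features` (data.frame), `comparison`
#'   (`cohort_comparison`), `correlations`, `labels`, `scheme` and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (is.character(config$input)) load_cohort_dir(config$input)
            else config$input
  lf <- validate_lung_function(cohort$lung_function)
  ids <- lf$patient_id
  if (!length(cohort$volumes) || !all(ids %in% names(cohort$volumes)))
    stop("cohort volumes missing for some patients in the lung-function table")
  cyl <- config$cylinder %||% cohort$cylinder %||%
    default_cylinder_spec(cohort$volumes[[1]])
  ref_id <- config$reference_id %||% cohort$reference_id %||% ids[1]
  if (!ref_id %in% ids) stop("reference patient '", ref_id, "' not in cohort")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(id, what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", what, "' for patient ", id, ": ",
           conditionMessage(e), call. = FALSE))
  }

  # the reference VOI fixes the grey-level bins for the whole cohort
  ref_vol <- cohort$volumes[[ref_id]]
  ref_mask <- stage(ref_id, "mask", make_cylinder_mask(ref_vol, cyl))
  ref_roi <- stage(ref_id, "extract", extract_roi(ref_vol, ref_mask))
  scheme <- stage(ref_id, "derive_levels",
                  derive_levels(ref_roi$value, config$n_levels,
                                provenance = ref_id))

  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    vol <- cohort$volumes[[id]]
    mask <- stage(id, "mask", make_cylinder_mask(vol, cyl))
    roi <- stage(id, "extract", extract_roi(vol, mask))
    q <- stage(id, "quantise",
               suppressWarnings(apply_quantisation(vol, scheme, mask)))
    emap <- stage(id, "entropy", compute_entropy_map(q))
    records[[i]] <- stage(id, "features",
                          build_feature_record(id, roi$value, emap, scheme,
                                               config$density_max,
                                               config$entropy_max))
    if (isTRUE(config$write_maps)) {
      write_entropy_map(emap, file.path(config$output_dir,
                                        paste0(id, "_entropy.nii.gz")))
      if (i == 1L) write_mask(mask, file.path(config$output_dir, "voi_mask.nii.gz"))
    }
    if (isTRUE(config$write_figures)) {
      h <- histogram2d(roi$value[!is.na(emap$entropy[mask$mask])],
                       entropy_values(emap),
                       scheme$edges, seq(0, log2(26), length.out = 17L))
      render_maps(emap, file.path(config$output_dir, "figures", id), hist = h)
    }
  }
  features <- do.call(rbind, records)

  labels <- label_fitness(lf, config$threshold_pct)
  comparison <- compare_cohorts(features, labels)
  correlations <- correlate_lung_function(features, lf)

  utils::write.csv(features, file.path(config$output_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(comparison, file.path(config$output_dir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(correlations,
                   file.path(config$output_dir, "correlations.csv"),
                   row.names = FALSE)
  write_scheme(scheme, file.path(config$output_dir, "scheme.json"))

  manifest <- list(
    package = "lungtexture",
    version = as.character(utils::packageVersion("lungtexture")),
    config_hash = config_hash(config),
    reference_id = ref_id,
    n_levels = scheme$n_levels,
    scheme_edges = scheme$edges,
    threshold_pct = config$threshold_pct,
    n_patients = length(ids),
    n_fit = sum(labels$label == "fit"),
    n_unfit = sum(labels$label == "unfit"))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  list(features = features, comparison = comparison,
       correlations = correlations, labels = labels, scheme = scheme,
       manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable md5 of the configuration's serialisable fields (in-memory cohorts
# hash their lung-function table rather than the voxel data)
config_hash <- function(config) {
  x <- unclass(config)
  if (!is.character(x$input)) x$input <- x$input$lung_function
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Render entropy maps and the density-entropy histogram as PNGs
#'
#' Writes one greyscale PNG per VOI slice of the entropy map (fixed
#' 0..log2(26) bit scale) and, when a [histogram2d] is supplied, a heatmap
#' with density on the x axis and entropy on the y axis.
#'
#' @param emap an `entropy_map`.
#' @param dir output directory (created if missing).
#' @param hist optional [histogram2d] of the same patient.
#' @return character vector of files written, invisibly.
#' @export
render_maps <- function(emap, dir, hist = NULL) {
  stopifnot(inherits(emap, "entropy_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  slices <- which(apply(emap$mask, 3, any))
  for (k in slices) {
    f <- file.path(dir, sprintf("entropy_slice%02d.png", k))
    grDevices::png(f, width = 480, height = 480)
    a <- emap$entropy[, , k]
    a[is.na(a)] <- 0
    graphics::image(a, zlim = c(0, log2(26)), col = grDevices::gray.colors(64),
                    axes = FALSE, main = sprintf("entropy (bits), slice %d", k))
    grDevices::dev.off()
    files <- c(files, f)
  }
  if (!is.null(hist)) {
    stopifnot(inherits(hist, "histogram2d"))
    f <- file.path(dir, "density_entropy_histogram.png")
    grDevices::png(f, width = 520, height = 480)
    graphics::image(x = hist$density_edges, y = hist$entropy_edges,
                    z = hist$counts, col = grDevices::hcl.colors(64, "YlOrRd",
                                                                 rev = TRUE),
                    xlab = "density (grey level)", ylab = "entropy (bits)",
                    main = "density-entropy histogram")
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
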