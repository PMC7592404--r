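#' Derive a fixed uniform quantisation scheme from a reference VOI
#'
#' Grey levels are quantised into `n_levels` equal-width bins spanning the
#' minimum-to-maximum range of a reference VOI (in the study design, the
#' apical VOI of a fit non-smoking patient). The resulting edges are then
#' held fixed and applied identically to every patient, so level k means the
#' same density everywhere in a cohort analysis.
#'
#' @param reference_values numeric vector of grey levels extracted from the
#'   reference VOI; must contain at least two distinct values.
#' @param n_levels number of quantisation levels (default 16, the study's
#'   setting).
#' @param provenance identifier of the reference VOI the edges came from.
#' @return An object of class `quant_scheme` with fields `n_levels`,
#'   `edges` (length `n_levels + 1`, strictly increasing, equally spaced)
#'   and `provenance`.
#' @export
derive_levels <- function(reference_values, n_levels = 16L,
                          provenance = "reference") {
  v <- as.numeric(reference_values)
  v <- v[is.finite(v)]
  if (length(v) < 2L) stop("need at least 2 finite reference values")
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L) stop("n_levels must be >= 2")
  lo <- min(v); hi <- max(v)
  if (hi <= lo)
    stop("reference values are constant (zero grey-level range); ",
         "cannot derive quantisation edges")
  quant_scheme(seq(lo, hi, length.out = n_levels + 1L), provenance)
}

#' Construct a quantisation scheme from explicit edges
#' @param edges strictly increasing, equally spaced grey-level bin edges.
#' @param provenance identifier of the reference the edges came from.
#' @export
quant_scheme <- function(edges, provenance = "reference") {
  edges <- as.numeric(edges)
  n <- length(edges) - 1L
  if (n < 2L) stop("need at least 3 edges")
  w <- diff(edges)
  if (any(w <= 0)) stop("edges must be strictly increasing")
  if (max(abs(w - w[1])) > 1e-9 * max(abs(edges)))
    stop("edges must be equally spaced (uniform quantisation)")
  structure(list(n_levels = n, edges = edges,
                 provenance = as.character(provenance)),
            class = "quant_scheme")
}

#' @export
print.quant_scheme <- function(x, ...) {
  cat(sprintf("<quant_scheme> %d uniform levels over [%.4g, %.4g] (from %s)\n",
              x$n_levels, x$edges[1], x$edges[x$n_levels + 1], x$provenance))
  invisible(x)
}

#' Apply a fixed quantisation scheme
#'
#' Maps grey value v to level k when `edges[k] <= v < edges[k+1]`; the top
#' edge itself maps to the top level. Values outside the reference range are
#' clipped to levels 1 / `n_levels` and a warning reports the out-of-range
#' fraction -- other patients' VOIs may legitimately exceed the reference
#' patient's range.
#'
#' With a numeric vector, returns the integer levels. With a [ct_volume] and
#' an [roi_mask], returns a `quant_volume`: an integer level array that is
#' `NA` outside the mask, plus the mask and the scheme, ready for the
#' co-occurrence entropy computation.
#'
#' @param x numeric vector of grey levels, or a [ct_volume].
#' @param scheme a `quant_scheme`.
#' @param mask an [roi_mask]; required when `x` is a volume.
#' @return Integer vector of levels in `1..n_levels`, or a `quant_volume`.
#' @export
apply_quantisation <- function(x, scheme, mask = NULL) {
  stopifnot(inherits(scheme, "quant_scheme"))
  if (inherits(x, "ct_volume")) {
    if (is.null(mask) || !inherits(mask, "roi_mask"))
      stop("quantising a volume requires an roi_mask")
    if (!identical(dim(x$voxels), mask$shape)) stop("mask/volume shape mismatch")
    lev <- array(NA_integer_, mask$shape)
    lev[mask$mask] <- quantise_values(x$voxels[mask$mask], scheme)
    return(structure(list(levels = lev, mask = mask$mask,
                          shape = mask$shape, spacing = mask$spacing,
                          scheme = scheme),
                     class = "quant_volume"))
  }
  quantise_values(as.numeric(x), scheme)
}

quantise_values <- function(v, scheme) {
  e <- scheme$edges
  n <- scheme$n_levels
  k <- findInterval(v, e, rightmost.closed = TRUE)
  out_of_range <- mean(v < e[1] | v > e[n + 1L])
  if (out_of_range > 0)
    warning(sprintf("%.2f%% of values outside the reference range [%.4g, %.4g]; clipped to end levels",
                    100 * out_of_range, e[1], e[n + 1L]))
  as.integer(pmin(pmax(k, 1L), n))
}

#' @export
print.quant_volume <- function(x, ...) {
  cat(sprintf("<quant_volume> %s, %d in-mask voxels, %d levels\n",
              paste(x$shape, collapse = " x "), sum(x$mask),
              x$scheme$n_levels))
  invisible(x)
}

#' Serialise / read a quantisation scheme as JSON
#'
#' @param scheme a `quant_scheme`.
#' @param path JSON path.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "quant_scheme"))
  jsonlite::write_json(list(n_levels = scheme$n_levels, edges = scheme$edges,
                            provenance = scheme$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Packaged synthetic reference quantisation scheme
#'
#' The study design fixes the 16 grey-level bins from the apical VOI of one
#' fit non-smoking patient. That scan is not available, so the package ships
#' a synthetic stand-in: edges derived from a pristine (severity 0) phantom
#' generated at seed 42 with default parameters, stored in
#' `extdata/synthetic_reference_scheme.json`. Use it when analysing phantom
#' cohorts without a designated reference patient; for real data derive your
#' own scheme from a suitable reference VOI.
#'
#' @return A `quant_scheme`.
#' @export
default_reference_scheme <- function() {
  read_scheme(system.file("extdata", "synthetic_reference_scheme.json",
                          package = "lungtexture", mustWork = TRUE))
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- quant_scheme(obj$edges, obj$provenance)
  if (!is.null(obj$n_levels) && sc$n_levels != obj$n_levels)
    stop("scheme file inconsistent: n_levels does not match edges")
  sc
}
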