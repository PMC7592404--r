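# Per-patient summary features: density (raw grey levels) and entropy (bits)
# reduced to mean / median / mode, moment analysis (skewness, excess
# kurtosis), the 2-D density-entropy histogram, and the size of the
# low-density low-entropy subregion that separates emphysematous from
# healthy parenchyma.

#' Mean, median and binned mode of a value distribution
#'
#' Mean is arithmetic; median uses the midpoint-of-two convention for even
#' n (the [stats::median] default). The mode of a continuous signal is
#' defined over bins: values are counted into the supplied bin edges
#' (clipping out-of-range values to the end bins, consistent with
#' quantisation) and the mode is the midpoint of the fullest bin, ties
#' resolved to the lowest bin.
#'
#' @param values non-empty numeric vector.
#' @param edges increasing bin edges used for the mode; defaults to 16
#'   equal-width bins over the data range.
#' @return named list `mean`, `median`, `mode`.
#' @export
summary_stats <- function(values, edges = NULL) {
  v <- as.numeric(values)
  if (length(v) == 0L || any(!is.finite(v))) stop("values must be non-empty and finite")
  if (is.null(edges)) {
    if (min(v) == max(v)) return(list(mean = v[1], median = v[1], mode = v[1]))
    edges <- seq(min(v), max(v), length.out = 17L)
  }
  edges <- as.numeric(edges)
  if (length(edges) < 2L || any(diff(edges) <= 0)) stop("edges must be increasing")
  nb <- length(edges) - 1L
  b <- findInterval(v, edges, rightmost.closed = TRUE)
  b <- pmin(pmax(b, 1L), nb)
  counts <- tabulate(b, nbins = nb)
  kmode <- which.max(counts)           # which.max takes the first (lowest) tie
  list(mean = mean(v), median = stats::median(v),
       mode = (edges[kmode] + edges[kmode + 1L]) / 2)
}

#' Moment analysis: skewness and excess kurtosis
#'
#' Population (biased) central-moment estimators: Fisher-Pearson skewness
#' `m3 / m2^1.5` and excess kurtosis `m4 / m2^2 - 3` (0 for a normal
#' distribution).
#'
#' @param values numeric vector, length >= 3, non-constant.
#' @return named list `skewness`, `kurtosis`.
#' @export
moments <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 3L) stop("need at least 3 values for a moment analysis")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) stop("values are constant (zero variance); moments undefined")
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  list(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

#' Two-dimensional density-entropy histogram
#'
#' Bins paired (density, entropy) voxel scores onto a grid: density on the
#' x axis, entropy on the y axis. Out-of-range points are clipped into the
#' end bins so every voxel is counted.
#'
#' @param density,entropy equal-length numeric vectors (one pair per voxel).
#' @param density_edges,entropy_edges increasing bin edges.
#' @return object of class `histogram2d`: `counts` matrix
#'   (density bins x entropy bins), plus the edges; `sum(counts)` equals the
#'   number of voxels.
#' @export
histogram2d <- function(density, entropy, density_edges, entropy_edges) {
  if (length(density) != length(entropy))
    stop("density and entropy must have equal length")
  bin1 <- function(v, e) {
    nb <- length(e) - 1L
    if (nb < 1L || any(diff(e) <= 0)) stop("invalid bin edges")
    pmin(pmax(findInterval(v, e, rightmost.closed = TRUE), 1L), nb)
  }
  bx <- bin1(density, density_edges)
  by <- bin1(entropy, entropy_edges)
  counts <- matrix(0L, length(density_edges) - 1L, length(entropy_edges) - 1L)
  t <- table(factor(bx, levels = seq_len(nrow(counts))),
             factor(by, levels = seq_len(ncol(counts))))
  counts[] <- as.integer(t)
  structure(list(counts = counts, density_edges = as.numeric(density_edges),
                 entropy_edges = as.numeric(entropy_edges)),
            class = "histogram2d")
}

#' Count voxels in the low-density low-entropy subregion
#'
#' Voxels that are both dark and homogeneous -- the histogram corner where
#' emphysematous bullae accumulate. A voxel counts iff
#' `density < density_max` AND `entropy < entropy_max` (strict).
#'
#' @param density,entropy equal-length numeric vectors.
#' @param density_max,entropy_max thresholds (grey levels / bits).
#' @return named list `count`, `fraction` (count / n).
#' @export
subregion_count <- function(density, entropy, density_max, entropy_max) {
  if (length(density) != length(entropy))
    stop("density and entropy must have equal length")
  inreg <- density < density_max & entropy < entropy_max
  list(count = sum(inreg), fraction = mean(inreg))
}

#' Reduce one patient's VOI to its feature record
#'
#' Density statistics use the raw grey levels of the original scan; entropy
#' statistics use the voxel-wise map computed on the quantised VOI, over
#' scored voxels only (isolated voxels carry no score). The density mode is
#' binned with the cohort's fixed quantisation edges; the entropy mode with
#' 16 equal bins over `[0, log2(26)]`. Subregion thresholds default to the
#' scheme's level-4/5 edge and 1 bit.
#'
#' @param patient_id patient identifier.
#' @param density numeric vector of raw in-mask grey levels, in mask order
#'   (as from [extract_roi]).
#' @param emap the patient's `entropy_map` on the same VOI.
#' @param scheme the cohort's fixed `quant_scheme` (for the density mode bins
#'   and the default density threshold).
#' @param density_max,entropy_max low-density / low-entropy subregion
#'   thresholds; `NULL` picks the defaults above.
#' @return one-row data.frame with columns `patient_id`, `density_mean`,
#'   `density_median`, `density_mode`, `entropy_mean`, `entropy_median`,
#'   `entropy_mode`, `density_skewness`, `density_kurtosis`,
#'   `entropy_skewness`, `entropy_kurtosis`, `subregion_count`,
#'   `subregion_fraction`.
#' @export
build_feature_record <- function(patient_id, density, emap, scheme,
                                 density_max = NULL, entropy_max = NULL) {
  stopifnot(inherits(emap, "entropy_map"), inherits(scheme, "quant_scheme"))
  density <- as.numeric(density)
  h_all <- emap$entropy[emap$mask]
  if (length(density) != length(h_all))
    stop("density vector and entropy map cover different VOIs (",
         length(density), " vs ", length(h_all), " voxels)")
  scored <- !is.na(h_all)
  h <- h_all[scored]
  if (!length(h)) stop("no scored voxels in entropy map")
  if (is.null(density_max)) density_max <- scheme$edges[5L]
  if (is.null(entropy_max)) entropy_max <- 1.0
  # degenerate (constant) signals get skewness 0 / kurtosis NA rather than an
  # error so that homogeneous phantoms still produce a record
  safe_moments <- function(v) {
    if (length(v) >= 3L && stats::var(v) > 0) moments(v)
    else list(skewness = 0, kurtosis = NA_real_)
  }
  ds <- summary_stats(density, edges = scheme$edges)
  es <- summary_stats(h, edges = seq(0, log2(26), length.out = 17L))
  dm <- safe_moments(density)
  em <- safe_moments(h)
  sub <- subregion_count(density[scored], h, density_max, entropy_max)
  data.frame(patient_id = as.character(patient_id),
             density_mean = ds$mean, density_median = ds$median,
             density_mode = ds$mode,
             entropy_mean = es$mean, entropy_median = es$median,
             entropy_mode = es$mode,
             density_skewness = dm$skewness, density_kurtosis = dm$kurtosis,
             entropy_skewness = em$skewness, entropy_kurtosis = em$kurtosis,
             subregion_count = sub$count, subregion_fraction = sub$fraction,
             stringsAsFactors = FALSE)
}

#' The feature columns compared between cohorts
#' @return character vector of feature column names in a feature table.
#' @export
feature_columns <- function() {
  c("density_mean", "density_median", "density_mode",
    "entropy_mean", "entropy_median", "entropy_mode",
    "density_skewness", "density_kurtosis",
    "entropy_skewness", "entropy_kurtosis",
    "subregion_count", "subregion_fraction")
}
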