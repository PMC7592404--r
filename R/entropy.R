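# Voxel-wise GLCM entropy over the 26-voxel neighbourhood.
#
# For each in-mask voxel a 16x16 co-occurrence matrix is accumulated from the
# 26 centre->neighbour pairs at displacement 1 in index space (the 13
# direction vectors and their negatives). Each pair increments cell
# (level(centre), level(neighbour)) and its transpose; counts are normalised
# to sum to 1 and the Shannon entropy of the cell probabilities, in bits, is
# the voxel's texture score. Homogeneous tissue (e.g. the interior of a
# bulla) scores near 0; mixed parenchyma (vessels/airways/alveoli) scores
# high.

# The 26 neighbour offsets, fixed order (used by fast path and single-voxel path)
neighbour_offsets <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
}

#' Local co-occurrence matrix of one voxel
#'
#' Builds the symmetrised grey-level co-occurrence probability matrix of a
#' single voxel from its (up to) 26 surrounding voxels. Neighbours outside
#' the grid or outside the VOI mask are skipped, so voxels at the cylinder
#' surface use fewer pairs rather than padded values.
#'
#' @param q a `quant_volume` (see [apply_quantisation]).
#' @param voxel integer length-3 index `(i, j, k)` of an in-mask voxel.
#' @return `n_levels` x `n_levels` matrix of probabilities summing to 1.
#'   Errors if the voxel is isolated (no valid neighbour).
#' @export
local_cooccurrence <- function(q, voxel) {
  stopifnot(inherits(q, "quant_volume"))
  voxel <- as.integer(voxel)
  d <- q$shape
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > d))
    stop("voxel index out of bounds")
  if (!q$mask[voxel[1], voxel[2], voxel[3]]) stop("voxel is not in the VOI mask")
  n <- q$scheme$n_levels
  k0 <- q$levels[voxel[1], voxel[2], voxel[3]]
  M <- matrix(0, n, n)
  offs <- neighbour_offsets()
  for (r in seq_len(nrow(offs))) {
    p <- voxel + offs[r, ]
    if (any(p < 1L) || any(p > d)) next
    if (!q$mask[p[1], p[2], p[3]]) next
    kn <- q$levels[p[1], p[2], p[3]]
    M[k0, kn] <- M[k0, kn] + 1
    M[kn, k0] <- M[kn, k0] + 1
  }
  s <- sum(M)
  if (s == 0)
    stop("voxel has no valid neighbour (isolated); it is excluded from entropy maps")
  M / s
}

#' Shannon entropy of a co-occurrence probability matrix
#'
#' `H = -sum over cells p > 0 of p * log2(p)`, in bits. Zero cells
#' contribute nothing.
#'
#' @param matrix a probability matrix summing to 1 (within 1e-8).
#' @return Entropy in bits.
#' @export
entropy_of <- function(matrix) {
  p <- as.numeric(matrix)
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8)
    stop("matrix is not normalised (sums to ", format(sum(p)), ")")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Compute the voxel-wise entropy map of a quantised VOI
#'
#' Scores every in-mask voxel with the entropy (bits) of its local
#' co-occurrence matrix. Isolated voxels (no in-mask neighbour) are flagged
#' and left `NA`; all others carry a score and the count of neighbour pairs
#' used (1..26).
#'
#' The per-voxel matrix has all its mass in one row and one column (the
#' centre voxel's level), so the whole map reduces to per-voxel neighbour
#' level histograms and is computed vectorised over the mask.
#'
#' @param q a `quant_volume`.
#' @return An object of class `entropy_map`: `entropy` (numeric array, `NA`
#'   outside mask and at isolated voxels), `valid_pairs` (integer array of
#'   neighbour counts), plus mask/shape/spacing.
#' @export
compute_entropy_map <- function(q) {
  stopifnot(inherits(q, "quant_volume"))
  if (!any(q$mask)) stop("empty VOI mask")
  d <- q$shape
  nlev <- q$scheme$n_levels
  dp <- d + 2L
  Lp <- array(NA_integer_, dp)
  Lp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- q$levels
  imask <- which(!is.na(Lp))
  nv <- length(imask)
  k_own <- Lp[imask]
  C <- matrix(0L, nv, nlev)      # per-voxel neighbour-level counts
  offs <- neighbour_offsets()
  s1 <- dp[1]; s12 <- dp[1] * dp[2]
  rows <- seq_len(nv)
  for (r in seq_len(nrow(offs))) {
    delta <- offs[r, 1] + offs[r, 2] * s1 + offs[r, 3] * s12
    neigh <- Lp[imask + delta]
    v <- !is.na(neigh)
    ij <- cbind(rows[v], neigh[v])
    C[ij] <- C[ij] + 1L
  }
  m <- rowSums(C)
  # symmetrised matrix: diagonal cell (k,k) holds 2*C[,k], off-diagonal pair
  # (k,j)/(j,k) holds C[,j] each; total mass 2m. Entropy collapses to
  #   H = -sum_j (C_j/m) log2(q_j),  q_j = C_j/(2m), except q_k = C_k/m.
  P <- C / m
  Q <- C / (2 * m)
  own <- cbind(rows, k_own)
  Q[own] <- C[own] / m
  term <- P * log2(Q)
  term[C == 0L] <- 0
  H <- -rowSums(term)
  H[m == 0L] <- NA_real_
  if (any(m == 0L))
    warning(sum(m == 0L), " isolated voxel(s) excluded from the entropy map")
  ent <- array(NA_real_, d)
  vp <- array(NA_integer_, d)
  ai <- arrayInd(imask, dp) - 1L   # drop the 1-voxel pad
  ent[ai] <- H
  vp[ai] <- m
  structure(list(entropy = ent, valid_pairs = vp, mask = q$mask,
                 shape = d, spacing = q$spacing),
            class = "entropy_map")
}

#' @export
print.entropy_map <- function(x, ...) {
  h <- x$entropy[x$mask]
  cat(sprintf("<entropy_map> %d scored voxels, entropy %.3f-%.3f bits (median %.3f)\n",
              sum(!is.na(h)), min(h, na.rm = TRUE), max(h, na.rm = TRUE),
              stats::median(h, na.rm = TRUE)))
  invisible(x)
}

#' Scored entropy values of a map
#'
#' @param emap an `entropy_map`.
#' @return numeric vector of entropy scores at scored (in-mask, non-isolated)
#'   voxels, in the same column-major order as [extract_roi].
#' @export
entropy_values <- function(emap) {
  stopifnot(inherits(emap, "entropy_map"))
  h <- emap$entropy[emap$mask]
  h[!is.na(h)]
}

#' Write an entropy map as NIfTI
#'
#' Out-of-mask voxels are written as 0 so the map overlays the source scan.
#' @param emap an `entropy_map`.
#' @param path output NIfTI path.
#' @export
write_entropy_map <- function(emap, path) {
  stopifnot(inherits(emap, "entropy_map"))
  a <- emap$entropy
  a[is.na(a)] <- 0
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- emap$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
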