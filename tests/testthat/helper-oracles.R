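# Independent brute-force oracles. These deliberately share no code with the
# package internals: explicit loops and direct formulas only.

# full 26-offset co-occurrence matrix of one voxel, by explicit enumeration
oracle_cooccurrence <- function(levels, mask, voxel, n_levels = 16L) {
  d <- dim(levels)
  M <- matrix(0, n_levels, n_levels)
  k0 <- levels[voxel[1], voxel[2], voxel[3]]
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    p <- voxel + c(di, dj, dk)
    if (any(p < 1) || any(p > d)) next
    if (!mask[p[1], p[2], p[3]]) next
    kn <- levels[p[1], p[2], p[3]]
    M[k0, kn] <- M[k0, kn] + 1
    M[kn, k0] <- M[kn, k0] + 1
  }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

oracle_entropy <- function(M) {
  h <- 0
  for (p in as.numeric(M)) if (p > 0) h <- h - p * log2(p)
  h
}

oracle_entropy_map <- function(levels, mask, n_levels = 16L) {
  d <- dim(levels)
  H <- array(NA_real_, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!mask[i, j, k]) next
    M <- oracle_cooccurrence(levels, mask, c(i, j, k), n_levels)
    if (!is.null(M)) H[i, j, k] <- oracle_entropy(M)
  }
  H
}

# linear-scan binning: smallest k with v < edges[k+1], clipping at the ends
oracle_bin <- function(v, edges) {
  n <- length(edges) - 1L
  vapply(v, function(x) {
    if (x < edges[1]) return(1L)
    if (x >= edges[n + 1L]) return(n)
    for (k in seq_len(n)) if (x >= edges[k] && x < edges[k + 1L]) return(k)
    n
  }, integer(1))
}

# direct central moments via explicit accumulation
oracle_moments <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- m3 <- m4 <- 0
  for (x in v) {
    m2 <- m2 + (x - mu)^2
    m3 <- m3 + (x - mu)^3
    m4 <- m4 + (x - mu)^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  c(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

oracle_hist2d <- function(x, y, xe, ye) {
  nx <- length(xe) - 1L; ny <- length(ye) - 1L
  counts <- matrix(0L, nx, ny)
  for (i in seq_along(x)) {
    bx <- oracle_bin(x[i], xe); by <- oracle_bin(y[i], ye)
    counts[bx, by] <- counts[bx, by] + 1L
  }
  counts
}

# build a quant_volume with prescribed integer levels through the public API
make_quant_volume <- function(levels, mask = NULL, n_levels = 16L) {
  if (is.null(mask)) mask <- array(TRUE, dim(levels))
  vol <- ct_volume(levels - 0.5)
  sc <- quant_scheme(seq(0, n_levels, by = 1), "test")
  apply_quantisation(vol, sc, structure(list(mask = mask, shape = dim(levels),
                                             spacing = c(1, 1, 1)),
                                        class = "roi_mask"))
}

random_levels <- function(d, n_levels = 16L) {
  array(sample.int(n_levels, prod(d), replace = TRUE), d)
}
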