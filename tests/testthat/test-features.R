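test_that("summary statistics follow the stated conventions", {
  s <- summary_stats(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$median, 2.5)
  s0 <- summary_stats(rep(3.7, 10))
  expect_equal(unlist(s0), c(mean = 3.7, median = 3.7, mode = 3.7))
  expect_error(summary_stats(numeric(0)), "non-empty")
})

test_that("summary statistics match sort/count oracles on random data", {
  set.seed(41)
  v <- rnorm(1000, 100, 25)
  edges <- seq(0, 200, by = 12.5)
  s <- summary_stats(v, edges)
  expect_equal(s$mean, sum(v) / length(v))
  sv <- sort(v)
  expect_equal(s$median, (sv[500] + sv[501]) / 2)
  counts <- tabulate(oracle_bin(v, edges), length(edges) - 1L)
  k <- which(counts == max(counts))[1]
  expect_equal(s$mode, (edges[k] + edges[k + 1]) / 2)
})

test_that("binned mode ties resolve to the lowest bin midpoint", {
  # two bins with equal counts: [0,1) and [2,3)
  s <- summary_stats(c(0.5, 0.5, 2.5, 2.5, 1.5), edges = 0:4)
  expect_equal(s$mode, 0.5)
})

test_that("moment analysis uses population central moments", {
  expect_equal(moments(1:5)$skewness, 0)
  expect_error(moments(rep(2, 10)), "constant")
  expect_error(moments(c(1, 2)), "at least 3")
  set.seed(42)
  v <- rgamma(1000, shape = 2)
  m <- moments(v)
  o <- oracle_moments(v)
  expect_equal(m$skewness, unname(o["skewness"]), tolerance = 1e-10)
  expect_equal(m$kurtosis, unname(o["kurtosis"]), tolerance = 1e-10)
})

test_that("moments are shift-invariant and statistics order-invariant", {
  set.seed(43)
  v <- rexp(400)
  m1 <- moments(v); m2 <- moments(v + 137.5)
  expect_equal(m1$skewness, m2$skewness, tolerance = 1e-8)
  expect_equal(m1$kurtosis, m2$kurtosis, tolerance = 1e-8)
  p <- sample(length(v))
  expect_equal(moments(v[p]), m1)
  expect_equal(summary_stats(v[p], 0:10)[c("mean", "median", "mode")],
               summary_stats(v, 0:10)[c("mean", "median", "mode")])
})

test_that("2-D histogram bins, clips and conserves counts", {
  h1 <- histogram2d(5, 0.5, density_edges = 0:10, entropy_edges = c(0, 1, 2))
  expect_equal(sum(h1$counts), 1L)
  expect_equal(h1$counts[6, 1], 1L)
  set.seed(44)
  x <- rnorm(500, 5, 4); y <- runif(500, -0.5, 3)
  h <- histogram2d(x, y, 0:10, c(0, 1, 2))
  expect_equal(sum(h$counts), 500L)
  expect_equal(h$counts, oracle_hist2d(x, y, 0:10, c(0, 1, 2)))
  expect_error(histogram2d(1:3, 1:2, 0:1, 0:1), "equal length")
})

test_that("subregion counting is a strict double threshold", {
  d <- c(1, 2, 3); e <- c(0.1, 0.2, 0.3)
  expect_equal(subregion_count(d, e, 10, 1)$count, 3)
  expect_equal(subregion_count(d, e, 10, 1)$fraction, 1)
  expect_equal(subregion_count(d, e, 0, 0)$count, 0)
  set.seed(45)
  x <- runif(300, 0, 300); y <- runif(300, 0, 4.7)
  got <- subregion_count(x, y, 120, 1.5)
  ref <- 0
  for (i in 1:300) if (x[i] < 120 && y[i] < 1.5) ref <- ref + 1
  expect_equal(got$count, ref)
  expect_equal(got$fraction, ref / 300)
  # monotone in both thresholds
  expect_lte(subregion_count(x, y, 100, 1.5)$count, got$count)
  expect_lte(subregion_count(x, y, 120, 1.0)$count, got$count)
})

test_that("a constant-density VOI yields all-zero entropy summaries", {
  vol <- ct_volume(array(100, c(6, 6, 6)))
  mask <- structure(list(mask = array(TRUE, c(6, 6, 6)), shape = c(6L, 6L, 6L),
                         spacing = c(1, 1, 1)), class = "roi_mask")
  sc <- derive_levels(c(0, 160))
  q <- apply_quantisation(vol, sc, mask)
  em <- compute_entropy_map(q)
  rec <- build_feature_record("P00", extract_roi(vol, mask)$value, em, sc)
  expect_equal(rec$entropy_mean, 0)
  expect_equal(rec$entropy_median, 0)
  expect_equal(rec$entropy_skewness, 0)
})

test_that("feature records satisfy their invariants on random phantoms", {
  set.seed(46)
  pp <- phantom_params(shape = c(20, 20, 14), spacing = c(2, 2, 2.5))
  sc <- NULL
  for (r in 1:8) {
    pp$severity <- runif(1, 0, 0.6)
    pp$seed <- 1000 + r
    ph <- generate_phantom(pp)
    spec <- default_cylinder_spec(pp, diameter_mm = 30)
    m <- make_cylinder_mask(ph$volume, spec)
    roi <- extract_roi(ph$volume, m)
    if (is.null(sc)) sc <- derive_levels(roi$value, provenance = "first")
    q <- suppressWarnings(apply_quantisation(ph$volume, sc, m))
    em <- compute_entropy_map(q)
    rec <- build_feature_record(paste0("R", r), roi$value, em, sc)
    expect_gte(rec$entropy_mean, 0); expect_lte(rec$entropy_mean, log2(26))
    expect_gte(rec$entropy_median, 0); expect_lte(rec$entropy_median, log2(26))
    expect_gte(rec$subregion_fraction, 0)
    expect_lte(rec$subregion_fraction, 1)
    expect_gte(rec$density_median, min(roi$value))
    expect_lte(rec$density_median, max(roi$value))
  }
})

test_that("an emphysematous phantom scores lower mean density than a fit one", {
  pp0 <- phantom_params(shape = c(24, 24, 14), spacing = c(2, 2, 2.5),
                        severity = 0, seed = 77)
  pp1 <- phantom_params(shape = c(24, 24, 14), spacing = c(2, 2, 2.5),
                        severity = 0.4, seed = 77)
  spec <- default_cylinder_spec(pp0)
  rec_of <- function(pp, sc = NULL) {
    ph <- generate_phantom(pp)
    m <- make_cylinder_mask(ph$volume, spec)
    roi <- extract_roi(ph$volume, m)
    if (is.null(sc)) sc <- derive_levels(roi$value)
    q <- suppressWarnings(apply_quantisation(ph$volume, sc, m))
    list(rec = build_feature_record("X", roi$value, compute_entropy_map(q), sc),
         sc = sc)
  }
  fit <- rec_of(pp0)
  emph <- rec_of(pp1, fit$sc)
  expect_gt(fit$rec$density_mean, emph$rec$density_mean)
})

test_that("adding a constant shifts location features and not shape features", {
  set.seed(47)
  v <- rnorm(800, 150, 40)
  sc <- derive_levels(v)
  sc2 <- quant_scheme(sc$edges + 50, "shifted")
  s1 <- summary_stats(v, sc$edges); s2 <- summary_stats(v + 50, sc2$edges)
  expect_equal(s2$mean, s1$mean + 50)
  expect_equal(s2$median, s1$median + 50)
  expect_equal(s2$mode, s1$mode + 50)
  m1 <- moments(v); m2 <- moments(v + 50)
  expect_equal(m1$skewness, m2$skewness, tolerance = 1e-9)
  expect_equal(m1$kurtosis, m2$kurtosis, tolerance = 1e-9)
})
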