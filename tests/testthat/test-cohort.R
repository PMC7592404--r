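lf_row <- function(fev1, tlco) data.frame(patient_id = "X", fev1_pct = fev1,
                                          tlco_pct = tlco)

test_that("fitness labelling applies the both-at-or-above-50 rule", {
  expect_equal(as.character(label_fitness(lf_row(85, 74))$label), "fit")
  expect_equal(as.character(label_fitness(lf_row(53, 43))$label), "unfit")
  expect_equal(as.character(label_fitness(lf_row(50, 50))$label), "fit")
  expect_equal(as.character(label_fitness(lf_row(110, 29))$label), "unfit")
  expect_equal(as.character(label_fitness(lf_row(49.9, 90))$label), "unfit")
})

test_that("fitness labelling is monotone in both lung-function values", {
  set.seed(51)
  for (r in 1:50) {
    f <- runif(1, 20, 90); t <- runif(1, 20, 90)
    l0 <- as.character(label_fitness(lf_row(f, t))$label)
    l1 <- as.character(label_fitness(lf_row(f + runif(1, 0, 40), t))$label)
    l2 <- as.character(label_fitness(lf_row(f, t + runif(1, 0, 40)))$label)
    if (l0 == "fit") expect_equal(c(l1, l2), c("fit", "fit"))
  }
  # alternative thresholds
  expect_equal(as.character(label_fitness(lf_row(55, 55), threshold_pct = 60)$label),
               "unfit")
})

test_that("Mann-Whitney exact p matches full rank enumeration", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)       # 2/20 assignments are as extreme
  expect_equal(mw$method, "exact")
  # independent check: enumerate all C(6,3) subsets directly
  Us <- apply(combn(6, 3), 2, function(s) sum(s) - 6)
  expect_equal(mw$p, 2 * min(mean(Us <= 0), mean(Us >= 0)))
})

test_that("identical samples give p = 1", {
  a <- c(2, 5, 5, 9, 12, 12, 12, 20, 31, 44, 50, 61, 70)
  mw <- mann_whitney_u(a, a)
  expect_equal(mw$p, 1)
  expect_equal(mw$U, length(a)^2 / 2)
})

test_that("approximate p agrees with the reference implementation at n = 29 vs 32", {
  set.seed(52)
  for (r in 1:10) {
    a <- rnorm(29, 0, 1); b <- rnorm(32, 0.3, 1.2)
    mine <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
  }
  # with heavy ties
  for (r in 1:5) {
    a <- sample(1:5, 29, replace = TRUE); b <- sample(2:6, 32, replace = TRUE)
    mine <- mann_whitney_u(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
  }
})

test_that("the test is symmetric and U_a + U_b = n_a * n_b without ties", {
  set.seed(53)
  a <- rnorm(15); b <- rnorm(20)
  m1 <- mann_whitney_u(a, b); m2 <- mann_whitney_u(b, a)
  expect_equal(m1$p, m2$p)
  expect_equal(m1$U + m2$U, 15 * 20)
})

test_that("p is invariant under strictly monotone transforms", {
  set.seed(54)
  a <- rlnorm(18); b <- rlnorm(25, 0.4)
  p0 <- mann_whitney_u(a, b)$p
  expect_equal(mann_whitney_u(log(a), log(b))$p, p0)
  expect_equal(mann_whitney_u(a^3, b^3)$p, p0)
})

test_that("Spearman correlation hits the rank-then-Pearson oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(correlate(x, exp(x)), 1.0)
  expect_equal(correlate(x, -x^3), -1.0)
  set.seed(55)
  u <- rnorm(200); v <- u + rnorm(200, 0, 2)
  expect_equal(correlate(u, v),
               stats::cor(rank(u), rank(v)), tolerance = 1e-10)
  expect_warning(r <- correlate(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(r))
  expect_error(correlate(1:4, 1:3), "equal length")
})

make_records <- function(vals, ids = sprintf("P%02d", seq_along(vals))) {
  data.frame(patient_id = ids, density_mean = vals, stringsAsFactors = FALSE)
}

make_labels <- function(groups, ids = sprintf("P%02d", seq_along(groups))) {
  data.frame(patient_id = ids,
             label = factor(groups, levels = c("fit", "unfit")),
             threshold_pct = 50, stringsAsFactors = FALSE)
}

test_that("cohort comparison holds its size under the null", {
  set.seed(56)
  groups <- c(rep("fit", 29), rep("unfit", 32))
  reject <- 0L
  for (r in 1:200) {
    cmp <- compare_cohorts(make_records(rnorm(61)), make_labels(groups),
                           features = "density_mean")
    if (cmp$p < 0.05) reject <- reject + 1L
  }
  # nominal 5% level: allow sampling slack around 10/200
  expect_lte(reject, 22L)
})

test_that("cohort comparison detects a strong separation", {
  set.seed(57)
  vals <- c(rnorm(29, 250, 30), rnorm(32, 190, 30))
  cmp <- compare_cohorts(make_records(vals),
                         make_labels(c(rep("fit", 29), rep("unfit", 32))))
  expect_lt(cmp$p[cmp$feature == "density_mean"], 0.05)
  expect_equal(cmp$n_fit[1], 29L)
  expect_equal(cmp$n_unfit[1], 32L)
  expect_gt(cmp$fit_mean[1], cmp$unfit_mean[1])
  # Holm column is an adjustment of the raw p, never smaller
  expect_true(all(cmp$p_holm >= cmp$p))
})

test_that("degenerate cohorts are rejected", {
  expect_error(compare_cohorts(make_records(rnorm(5)),
                               make_labels(rep("fit", 5))),
               "both cohorts")
  expect_error(compare_cohorts(make_records(rnorm(5)),
                               make_labels(c("fit", "unfit"),
                                           ids = c("P01", "P02"))),
               "missing fitness label")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("feature / lung-function correlations are computed per feature", {
  set.seed(58)
  lf <- data.frame(patient_id = sprintf("P%02d", 1:20),
                   fev1_pct = runif(20, 30, 110),
                   tlco_pct = runif(20, 30, 100))
  rec <- make_records(lf$fev1_pct * 2 + rnorm(20, 0, 1e-6), ids = lf$patient_id)
  out <- correlate_lung_function(rec, lf)
  expect_equal(out$feature, "density_mean")
  expect_equal(out$rho_fev1, 1.0, tolerance = 1e-6)
})
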