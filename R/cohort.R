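# Fit/unfit labelling from lung function, two-sample Mann-Whitney
# comparison of feature distributions, and Spearman correlation of features
# against lung function.

#' Label patients fit or unfit for radical radiotherapy
#'
#' A patient is fit iff BOTH FEV1 and TLCO are at or above the threshold
#' (default 50% of predicted); a single value below the threshold makes the
#' patient unfit. Alternative thresholds are supported via `threshold_pct`.
#'
#' @param lf lung-function data.frame (`patient_id`, `fev1_pct`, `tlco_pct`).
#' @param threshold_pct percent-of-predicted threshold, default 50.
#' @return data.frame `patient_id`, `label` (factor fit/unfit),
#'   `threshold_pct`.
#' @export
label_fitness <- function(lf, threshold_pct = 50) {
  lf <- validate_lung_function(lf)
  fit <- lf$fev1_pct >= threshold_pct & lf$tlco_pct >= threshold_pct
  data.frame(patient_id = lf$patient_id,
             label = factor(ifelse(fit, "fit", "unfit"),
                            levels = c("fit", "unfit")),
             threshold_pct = threshold_pct,
             stringsAsFactors = FALSE)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling. The p-value is exact by full
#' enumeration of rank assignments when the pooled sample has at most 12
#' observations and no ties; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used (the usual
#' large-sample form). The reported U is for the first sample.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return named list `U`, `p` (two-sided), `method`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)                       # midranks
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  if (N <= 12L && !ties) {
    # exact null distribution of U by enumerating all C(N, na) assignments
    combs <- utils::combn(N, na)
    r0 <- rank(pooled)                     # no ties: a permutation of 1..N
    Us <- colSums(matrix(r0[combs], nrow = na)) - na * (na + 1) / 2
    p <- 2 * min(mean(Us <= U), mean(Us >= U))
    return(list(U = U, p = min(p, 1), method = "exact"))
  }
  mu <- na * nb / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties; the skew-robust companion to the
#' Mann-Whitney comparison. Constant input has no defined rank correlation
#' and returns `NA` with a warning.
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
correlate <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant input: rank correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Compare feature distributions between fit and unfit cohorts
#'
#' One two-sided Mann-Whitney test per feature, plus group means/medians and
#' sizes. Raw p-values are the primary output (one test per feature, as
#' reported); a Holm-adjusted column is added alongside, clearly labelled.
#'
#' @param records feature table (one row per patient, as from
#'   [build_feature_record]).
#' @param labels fitness labels (as from [label_fitness]); every patient in
#'   `records` must be labelled and both groups must be non-empty.
#' @param features feature columns to compare; default [feature_columns()]
#'   intersected with what `records` contains.
#' @return data.frame of class `cohort_comparison`: one row per feature with
#'   `U`, `p`, `p_holm`, `fit_mean`, `fit_median`, `unfit_mean`,
#'   `unfit_median`, `n_fit`, `n_unfit`.
#' @export
compare_cohorts <- function(records, labels, features = NULL) {
  if (is.null(features)) features <- intersect(feature_columns(), names(records))
  if (!length(features)) stop("no feature columns to compare")
  m <- match(records$patient_id, labels$patient_id)
  if (anyNA(m))
    stop("missing fitness label for patient(s): ",
         paste(records$patient_id[is.na(m)], collapse = ", "))
  lab <- labels$label[m]
  if (!all(c("fit", "unfit") %in% lab))
    stop("both cohorts must be non-empty (got ",
         sum(lab == "fit"), " fit, ", sum(lab == "unfit"), " unfit)")
  res <- lapply(features, function(f) {
    af <- records[[f]][lab == "fit"]
    au <- records[[f]][lab == "unfit"]
    mw <- mann_whitney_u(af, au)
    data.frame(feature = f, U = mw$U, p = mw$p,
               fit_mean = mean(af), fit_median = stats::median(af),
               unfit_mean = mean(au), unfit_median = stats::median(au),
               n_fit = length(af), n_unfit = length(au),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out <- out[, c("feature", "U", "p", "p_holm", "fit_mean", "fit_median",
                 "unfit_mean", "unfit_median", "n_fit", "n_unfit")]
  class(out) <- c("cohort_comparison", "data.frame")
  out
}

#' Correlate features with lung function
#'
#' Spearman correlation of each feature against FEV1 and TLCO %-predicted
#' across the whole cohort.
#'
#' @param records feature table.
#' @param lf lung-function table covering every patient in `records`.
#' @param features feature columns; default as in [compare_cohorts].
#' @return data.frame `feature`, `rho_fev1`, `rho_tlco`.
#' @export
correlate_lung_function <- function(records, lf, features = NULL) {
  if (is.null(features)) features <- intersect(feature_columns(), names(records))
  lf <- validate_lung_function(lf)
  m <- match(records$patient_id, lf$patient_id)
  if (anyNA(m)) stop("missing lung function for patient(s): ",
                     paste(records$patient_id[is.na(m)], collapse = ", "))
  do.call(rbind, lapply(features, function(f) {
    data.frame(feature = f,
               rho_fev1 = correlate(records[[f]], lf$fev1_pct[m]),
               rho_tlco = correlate(records[[f]], lf$tlco_pct[m]),
               stringsAsFactors = FALSE)
  }))
}
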