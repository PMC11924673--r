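# Reproducibility gate: consistency ICC, coefficient of variation, and
# the ICC >= 0.75 / CV <= 10% feature filter.

#' Consistency intraclass correlation (two-way mixed effects, single rater)
#'
#' ICC(C,1) from the two-way ANOVA without interaction:
#' (MSR - MSE) / (MSR + (k - 1) MSE), where MSR is the between-subject
#' and MSE the residual mean square. Fixed per-rater shifts do not affect
#' this form. Repeatability labels: poor (< 0.5), fair (0.50-0.75),
#' good (0.75-0.90), excellent (0.90-1).
#'
#' @param ratings subjects x raters numeric matrix, no missing cells
#' @return list(icc, ms_rows, ms_error, k, n, label, degenerate)
#' @export
icc_consistency <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stopf("missing cells in the ratings matrix")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L) stopf("need at least 2 subjects and 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_total == 0) {
    icc <- 1
    degenerate <- TRUE
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    degenerate <- FALSE
  }
  label <- if (icc < 0.5) "poor" else if (icc < 0.75) "fair" else
    if (icc < 0.90) "good" else "excellent"
  list(icc = icc, ms_rows = msr, ms_error = mse, k = k, n = n,
       label = label, degenerate = degenerate)
}

#' Coefficient of variation
#'
#' sd / |mean| of a set of repeated measurements; |mean| is used so that
#' sign-varying filtered features get a meaningful dispersion measure.
#' A near-zero mean is flagged unstable (Inf), which fails the gate.
#' @param values numeric vector of repeated measurements
#' @return scalar CV (possibly Inf)
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  s <- stats::sd(values)
  if (abs(m) < 1e-12 * max(1, s)) return(Inf)
  s / abs(m)
}

# per-feature CV: per-case sd/|mean| across measurements, median over cases
feature_cv <- function(case_by_meas) {
  per_case <- apply(case_by_meas, 1, coefficient_of_variation)
  stats::median(per_case)
}

#' Reproducibility gate over a reader study
#'
#' For every feature: the intra-observer ICC compares reader 1's two
#' passes, the inter-observer ICC compares reader 1 pass 1 with reader 2
#' pass 1, and the CV is the median over cases of the per-case sd/|mean|
#' across all measurements. A feature passes iff both ICCs reach
#' `icc_threshold` and the CV is at most `cv_threshold`.
#'
#' @param tables named list of feature tables (same cases, same feature
#'   columns) with names "r<reader>p<pass>"; needs at least r1p1, r1p2,
#'   r2p1
#' @param icc_threshold,cv_threshold gate thresholds (0.75, 0.10)
#' @return data.frame(feature, icc_intra, icc_inter, cv, passed)
#' @export
reproducibility_gate <- function(tables, icc_threshold = 0.75,
                                 cv_threshold = 0.10) {
  need <- c("r1p1", "r1p2", "r2p1")
  if (!all(need %in% names(tables))) {
    stopf("tables must include %s", paste(need, collapse = ", "))
  }
  feats <- feature_columns(tables[[1]])
  for (tb in tables) {
    if (!identical(feature_columns(tb), feats)) {
      stopf("feature catalogs differ between reader tables")
    }
    if (!identical(tb$case_id, tables[[1]]$case_id)) {
      stopf("case sets differ between reader tables")
    }
  }
  res <- lapply(feats, function(f) {
    intra <- icc_consistency(cbind(tables$r1p1[[f]], tables$r1p2[[f]]))
    inter <- icc_consistency(cbind(tables$r1p1[[f]], tables$r2p1[[f]]))
    all_meas <- do.call(cbind, lapply(tables, function(tb) tb[[f]]))
    cv <- feature_cv(all_meas)
    data.frame(feature = f, icc_intra = intra$icc, icc_inter = inter$icc,
               cv = cv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$passed <- out$icc_intra >= icc_threshold &
    out$icc_inter >= icc_threshold & out$cv <= cv_threshold
  out
}
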