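checkSample <- function(x, label) {
  if (length(x) < 2L)
    stop(sprintf("sample '%s' needs at least 2 observations", label), call. = FALSE)
  if (var(x) == 0)
    stop(sprintf("sample '%s' has zero variance (degenerate)", label), call. = FALSE)
}

#' F-test for equality of variances
#'
#' The variance gate of the group-comparison procedure: the ratio of sample
#' variances `F = s_x^2 / s_y^2` is referred to an F distribution with
#' `(n_x - 1, n_y - 1)` degrees of freedom; the two-sided p-value is
#' `2 * min(P(F <= f), P(F >= f))` capped at 1. Variances are declared equal
#' when `p > gateLevel`, which routes the downstream comparison to the
#' pooled-variance Student t-test rather than Welch's t-test.
#'
#' @param x,y numeric vectors, each of length >= 2 with non-zero variance.
#' @param gateLevel significance level of the gate; default 0.05, the same
#'   level used for the group comparisons themselves.
#' @return list with `f_stat`, `df1`, `df2`, `f_p`, `variance_equal`.
#' @export
#' @examples
#' fVarianceTest(c(1, 2, 3), c(4, 5, 6))
fVarianceTest <- function(x, y, gateLevel = 0.05) {
  checkSample(x, "x"); checkSample(y, "y")
  df1 <- length(x) - 1L
  df2 <- length(y) - 1L
  f <- var(x) / var(y)
  lower <- pf(f, df1, df2)
  p <- min(1, 2 * min(lower, 1 - lower))
  list(f_stat = f, df1 = df1, df2 = df2, f_p = p,
       variance_equal = p > gateLevel)
}

#' Two-sample t-test (pooled or Welch)
#'
#' With `equalVar = TRUE`, the pooled-variance Student t statistic with
#' `n_x + n_y - 2` degrees of freedom; otherwise Welch's statistic with
#' Welch-Satterthwaite degrees of freedom. Two-sided p-value in both cases.
#'
#' @param x,y numeric vectors, each of length >= 2 with non-zero variance.
#' @param equalVar logical, typically the `variance_equal` verdict of
#'   [fVarianceTest()].
#' @return list with `t_stat`, `df`, `p_value`, `test_used`.
#' @export
#' @examples
#' twoSampleT(c(1, 2, 3), c(4, 5, 6), equalVar = TRUE)
twoSampleT <- function(x, y, equalVar) {
  checkSample(x, "x"); checkSample(y, "y")
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  d <- mean(x) - mean(y)
  if (equalVar) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    t <- d / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2x <- vx / nx
    se2y <- vy / ny
    t <- d / sqrt(se2x + se2y)
    df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  }
  p <- 2 * pt(-abs(t), df)
  list(t_stat = t, df = df, p_value = p,
       test_used = if (equalVar) "student" else "welch")
}

## Map a p-value to the significance call. Boundaries are deliberate:
## p == 0.05 is significant, p == 0.10 is ns, strictly between is borderline.
significanceCall <- function(p) {
  if (p <= 0.05) "significant" else if (p < 0.10) "borderline" else "ns"
}

#' Pairwise variance-gated group comparisons across the panel
#'
#' For every biomarker and each of the three group pairs
#' (localized vs control, metastatic vs control, localized vs metastatic),
#' runs the F-test gate and then the pooled or Welch t-test, and classifies
#' the result as significant (`p <= 0.05`), borderline
#' (`0.05 < p < 0.10`) or ns. Raw p-values are reported; no multiple-testing
#' adjustment is applied.
#'
#' @param x a labeled [ActivitySet-class] with all three groups present.
#' @param gateLevel level of the F gate (default 0.05).
#' @return data.frame with one row per biomarker x pair: `biomarker`, `pair`,
#'   `f_stat`, `f_p`, `variance_equal`, `test_used`, `t_stat`, `df`,
#'   `p_value`, `call`.
#' @export
#' @examples
#' cohort <- generateCohort(cohortConfig(seed = 1L))
#' head(compareGroups(cohort))
compareGroups <- function(x, gateLevel = 0.05) {
  stopifnot(is(x, "ActivitySet"))
  act <- activityMatrix(x)
  grp <- as.character(sampleGroups(x))
  missing <- setdiff(CLASS_LEVELS, unique(grp[!is.na(grp)]))
  if (length(missing))
    stop(sprintf("missing groups: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  pairs <- list(
    "localized-vs-control"    = c("localized", "healthy"),
    "metastatic-vs-control"   = c("metastatic", "healthy"),
    "localized-vs-metastatic" = c("localized", "metastatic")
  )
  rows <- vector("list", ncol(act) * length(pairs))
  i <- 0L
  for (bm in colnames(act)) {
    for (pn in names(pairs)) {
      a <- act[grp == pairs[[pn]][1L] & !is.na(grp), bm]
      b <- act[grp == pairs[[pn]][2L] & !is.na(grp), bm]
      fr <- fVarianceTest(a, b, gateLevel = gateLevel)
      tr <- twoSampleT(a, b, equalVar = fr$variance_equal)
      i <- i + 1L
      rows[[i]] <- data.frame(
        biomarker = bm, pair = pn,
        f_stat = fr$f_stat, f_p = fr$f_p,
        variance_equal = fr$variance_equal, test_used = tr$test_used,
        t_stat = tr$t_stat, df = tr$df, p_value = tr$p_value,
        call = significanceCall(tr$p_value), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a group-comparison table to CSV
#'
#' @param comparison data.frame from [compareGroups()].
#' @param path output file path.
#' @export
writeComparisonCsv <- function(comparison, path) {
  write.csv(comparison, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
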