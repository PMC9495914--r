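#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided p value. This is the test used for cross-group
#' comparisons of MTR values (test vs control cohort at a time point, and
#' cell-wise in [significance_map()]).
#'
#' @param a,b Numeric samples, n >= 2 each, with nonzero variance in at
#'   least one.
#' @return Object of class `cest_test`: `statistic`, `p_value`, `df`,
#'   `n1`, `n2`, `method`.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("welch_t: need at least 2 observations per group")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("welch_t: both groups have zero variance")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 n1 = length(a), n2 = length(b), method = "welch"),
            class = "cest_test")
}

#' Student's paired t-test
#'
#' One-sample t test on within-subject differences (`post - pre`), df =
#' n - 1, two-sided p. Used to compare each subject's MTR at a later time
#' point against its own pre-injection value.
#'
#' @param pre,post Equal-length paired samples, n >= 2; the differences
#'   must not all be identical.
#' @return A `cest_test`.
#' @export
paired_t <- function(pre, post) {
  pre <- as.numeric(pre); post <- as.numeric(post)
  if (length(pre) != length(post)) stop("paired_t: length mismatch")
  if (length(pre) < 2) stop("paired_t: need at least 2 pairs")
  if (stats::var(post - pre) == 0)
    stop("paired_t: zero-variance differences")
  tt <- stats::t.test(post, pre, paired = TRUE)
  structure(list(statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 n1 = length(pre), n2 = length(post), method = "paired"),
            class = "cest_test")
}

#' Cell-wise significance map of partial Z-spectral data
#'
#' Welch's t test per (offset, sweep) cell between the per-subject MTR
#' values of the test and control cohorts; cells with p < alpha are
#' flagged. No multiplicity correction is applied by default (mirroring
#' common practice for these exploratory maps; interpret accordingly). A
#' Benjamini-Hochberg adjustment over all cells can be switched on.
#'
#' @param test_maps,control_maps `partial_map` objects, or lists of
#'   per-subject matrices with matching dimensions.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Object of class `significance_map`: `significant` (logical
#'   matrix), `p_values` (matrix), `alpha`.
#' @export
significance_map <- function(test_maps, control_maps, alpha = 0.05,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(alpha >= 0, alpha <= 1)
  tm <- if (inherits(test_maps, "partial_map")) test_maps$subject_maps
        else test_maps
  cm <- if (inherits(control_maps, "partial_map")) control_maps$subject_maps
        else control_maps
  d <- dim(tm[[1]])
  for (m in c(tm, cm))
    if (!all(dim(m) == d)) stop("significance_map: axis mismatch")
  ta <- simplify2array(tm); ca <- simplify2array(cm)
  p <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      p[i, j] <- welch_t(ta[i, j, ], ca[i, j, ])$p_value
  if (adjust == "BH") p[] <- stats::p.adjust(as.vector(p), method = "BH")
  structure(list(significant = !is.na(p) & p < alpha, p_values = p,
                 alpha = alpha),
            class = "significance_map")
}

#' Tidy data.frame of test results
#' @param results Named list of `cest_test`.
#' @return data.frame: comparison, method, t, df, p, n1, n2.
#' @export
tests_df <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(comparison = nm, method = r$method, t = r$statistic,
               df = r$df, p = r$p_value, n1 = r$n1, n2 = r$n2)
  }))
}

#' @export
print.cest_test <- function(x, ...) {
  cat(sprintf("<%s t-test> t = %.3f, df = %.2f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$df, x$p_value, x$n1, x$n2))
  invisible(x)
}
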