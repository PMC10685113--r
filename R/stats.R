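#' Two-group comparison
#'
#' Welch's unpaired t-test or the Mann-Whitney U test (exact where sample
#' sizes permit and there are no ties, otherwise the tie-corrected normal
#' approximation), as used to contrast kinetics and morphology between
#' imaging temperatures.
#'
#' @param a,b Numeric samples (each >= 2 values for the t-test, >= 1 for
#'   Mann-Whitney).
#' @param test `"unpaired_t"` or `"mann_whitney"`.
#' @return A list of class `group_comparison` with `statistic`, `p_value`,
#'   `n1`, `n2`, `method`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$statistic  # Welch t = -3.674
#' @export
compare_groups <- function(a, b, test = c("unpaired_t", "mann_whitney")) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("compare_groups: samples must be finite")
  if (test == "unpaired_t") {
    if (length(a) < 2 || length(b) < 2)
      stop("compare_groups: the t-test needs >= 2 values per group")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      # degenerate constant samples: define t = 0, p = 1 when means agree
      if (mean(a) == mean(b)) {
        res <- list(statistic = 0, p_value = 1)
      } else {
        res <- list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0)
      }
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      res <- list(statistic = unname(tt$statistic), p_value = tt$p.value)
    }
    method <- "Welch unpaired t-test"
  } else {
    if (length(a) < 1 || length(b) < 1)
      stop("compare_groups: Mann-Whitney needs >= 1 value per group")
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    res <- list(statistic = unname(wt$statistic), p_value = wt$p.value)
    method <- "Mann-Whitney U test"
  }
  structure(c(res, list(n1 = length(a), n2 = length(b), method = method)),
            class = "group_comparison")
}

#' Compare two least-squares regressions
#'
#' Fits ordinary least-squares lines to two groups of paired observations
#' and tests either slope equality (via the group-by-covariate interaction
#' of the pooled model) or, assuming a common slope, the group intercept
#' difference (analysis of covariance: the group main effect with a shared
#' covariate slope). This is the height-versus-width comparison used for
#' baseline (slopes) and stimulated (ANCOVA intercepts) transient kinetics.
#'
#' @param x1,y1 First group's covariate and response (>= 3 points).
#' @param x2,y2 Second group's covariate and response (>= 3 points).
#' @param mode `"slopes"` or `"intercepts"`.
#' @return A list of class `regression_comparison` with per-group
#'   coefficients (`fit1`, `fit2` as `c(intercept, slope)`), the tested
#'   `difference`, `statistic` (t), `p_value`, and `mode`.
#' @export
compare_regressions <- function(x1, y1, x2, y2, mode = c("slopes", "intercepts")) {
  mode <- match.arg(mode)
  if (length(x1) < 3 || length(x2) < 3)
    stop("compare_regressions: each group needs >= 3 points")
  if (length(x1) != length(y1) || length(x2) != length(y2))
    stop("compare_regressions: x and y lengths differ")
  if (stats::var(x1) == 0 || stats::var(x2) == 0)
    stop("compare_regressions: degenerate (constant) covariate")

  x <- c(x1, x2)
  y <- c(y1, y2)
  g <- factor(rep(c("a", "b"), c(length(x1), length(x2))))
  f1 <- stats::lm(y1 ~ x1)
  f2 <- stats::lm(y2 ~ x2)

  if (mode == "slopes") {
    fit <- stats::lm(y ~ x * g)
    co <- summary(fit)$coefficients
    row <- "x:gb"
    difference <- unname(stats::coef(fit)[row])
  } else {
    fit <- stats::lm(y ~ x + g)
    co <- summary(fit)$coefficients
    row <- "gb"
    difference <- unname(stats::coef(fit)[row])
  }
  structure(list(fit1 = unname(stats::coef(f1)), fit2 = unname(stats::coef(f2)),
                 difference = difference,
                 statistic = unname(co[row, "t value"]),
                 p_value = unname(co[row, "Pr(>|t|)"]),
                 mode = mode),
            class = "regression_comparison")
}
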