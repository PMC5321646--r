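#' Bland-Altman agreement in percent difference
#'
#' Per-pair percent difference of `estimates` against designated reference
#' values, summarized as the mean with 95% limits of agreement
#' (mean +/- 1.96 SD). By convention the denominator is the reference
#' method's value (`denominator = "reference"`); the pair-mean denominator
#' of the classical Bland-Altman plot is available as an option.
#'
#' @param estimates Numeric vector of the method under comparison.
#' @param reference_estimates Equal-length vector of the reference method
#'   (must be positive when used as denominator).
#' @param denominator `"reference"` (default) or `"mean"`.
#' @return Object of class `agreement_report`: `mean_pct_diff`, `loa_low`,
#'   `loa_high`, `sd_pct_diff`, `n_pairs`, and the per-pair `pct_diff`.
#' @export
bland_altman <- function(estimates, reference_estimates,
                         denominator = c("reference", "mean")) {
  denominator <- match.arg(denominator)
  a <- as.numeric(estimates)
  b <- as.numeric(reference_estimates)
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  den <- if (denominator == "reference") b else (a + b) / 2
  if (any(!is.finite(den)) || any(den == 0)) {
    stop("denominator values must be nonzero and finite")
  }
  d <- 100 * (a - b) / den
  m <- mean(d)
  s <- stats::sd(d)
  if (length(d) == 1L) s <- 0
  structure(list(mean_pct_diff = m, sd_pct_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n_pairs = length(d), pct_diff = d,
                 denominator = denominator),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %.3g%% (95%% LoA %.3g to %.3g), n = %d\n",
              x$mean_pct_diff, x$loa_low, x$loa_high, x$n_pairs))
  invisible(x)
}

#' Percent bias against known truth
#'
#' `100 * (estimate - truth) / truth` per item, with the overall bias the
#' mean across items.
#'
#' @param estimates Numeric vector.
#' @param truths Equal-length vector of positive true values.
#' @return List with `per_item` and `overall`.
#' @export
percent_bias <- function(estimates, truths) {
  a <- as.numeric(estimates)
  b <- as.numeric(truths)
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(!is.finite(b)) || any(b == 0)) stop("truths must be nonzero")
  d <- 100 * (a - b) / b
  list(per_item = d, overall = mean(d))
}

#' Ordinary least-squares regression with correlation
#'
#' Simple linear regression `y ~ x` reporting slope, intercept, Pearson r
#' and the two-sided p-value for the slope.
#'
#' @param x,y Numeric vectors, `n >= 3`, `x` non-degenerate.
#' @return List with `slope`, `intercept`, `r`, `p`.
#' @export
linear_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x is degenerate (zero variance)")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(sign(stats::coef(fit)[2]) * sqrt(sm$r.squared)),
       p = unname(sm$coefficients[2, 4]))
}

#' Holm (step-down Bonferroni) multiple-comparison correction
#'
#' Sorts the p-values ascending, compares the i-th smallest against
#' `alpha / (m - i + 1)`, stops at the first failure; adjusted p-values are
#' the running maximum of `(m - i + 1) * p_(i)` capped at 1 (the standard
#' Holm adjustment, as computed by `p.adjust`).
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @param alpha Familywise error rate (default 0.05).
#' @return List with `adjusted` (same order as input) and `reject`
#'   (logical).
#' @export
holm_correct <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p, method = "holm")
  list(adjusted = adj, reject = adj <= alpha)
}
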