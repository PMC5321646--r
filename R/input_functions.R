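#' Fit a single-exponential parent-fraction model
#'
#' Fits `f(t) = offset + amplitude * exp(-rate * t)` to measured parent
#' (unmetabolized) fraction samples by least squares. The fitted curve is
#' clipped to \[0, 1\] on evaluation. A pure single exponential (no plateau)
#' is available with `offset = FALSE`: parent fractions of some tracers decay
#' to zero, others plateau well above it, and the data decide poorly with few
#' metabolite samples, so both forms are exposed.
#'
#' @param samples A [sampled_curve()] of kind `"fraction"`; at least 3
#'   samples with positive times.
#' @param offset Logical; include the plateau term (default `TRUE`).
#' @return Object of class `parent_fraction_model` with fields `offset`,
#'   `amplitude`, `rate` (min^-1) and `rss`.
#' @export
fit_parent_fraction <- function(samples, offset = TRUE) {
  stopifnot(inherits(samples, "sampled_curve"))
  if (samples$kind != "fraction") stop("samples must be of kind 'fraction'")
  tt <- samples$times
  yy <- samples$values
  if (length(tt) < 3L) stop("insufficient data: need at least 3 samples")
  if (any(tt <= 0)) stop("sample times must be positive")

  resid_fun <- function(par) {
    off <- if (offset) par[1] else 0
    amp <- par[if (offset) 2 else 1]
    rate <- par[if (offset) 3 else 2]
    off + amp * exp(-rate * tt) - yy
  }
  lower <- if (offset) c(0, 0, 0) else c(0, 0)
  upper <- if (offset) c(1, 1, 10) else c(1, 10)
  starts <- list(c(min(yy), max(yy) - min(yy), 0.05),
                 c(0.1, 0.8, 0.02), c(0, 1, 0.1), c(0.5, 0.5, 0.01))
  best <- NULL
  for (s in starts) {
    s <- if (offset) s else s[-1]
    fit <- tryCatch(
      minpack.lm::nls.lm(pmin(pmax(s, lower), upper), lower, upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss - 0 ||
          (rss < best$rss)) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("fit failure: parent-fraction model did not converge")
  par <- best$fit$par
  out <- list(offset = if (offset) par[1] else 0,
              amplitude = par[if (offset) 2 else 1],
              rate = par[if (offset) 3 else 2],
              rss = best$rss)
  class(out) <- "parent_fraction_model"
  out
}

#' Evaluate a parent-fraction model
#'
#' @param model A `parent_fraction_model` (or a bare list with `offset`,
#'   `amplitude`, `rate`).
#' @param t Times in minutes.
#' @return Predicted parent fraction, clipped to \[0, 1\].
#' @export
predict_parent_fraction <- function(model, t) {
  f <- model$offset + model$amplitude * exp(-model$rate * t)
  pmin(pmax(f, 0), 1)
}

#' @export
print.parent_fraction_model <- function(x, ...) {
  cat(sprintf(
    "<parent_fraction_model> f(t) = %.4g + %.4g * exp(-%.4g t), rss = %.3g\n",
    x$offset, x$amplitude, x$rate, x$rss))
  invisible(x)
}

#' Metabolite-correct a total plasma curve
#'
#' Multiplies a total-plasma curve pointwise by the predicted parent
#' fraction, yielding the parent-plasma (metabolite-corrected) input
#' function. Because the fraction is at most 1, correction never increases a
#' plasma value.
#'
#' @param plasma_total [sampled_curve()] of kind `"plasma_total"`.
#' @param model A `parent_fraction_model` from [fit_parent_fraction()].
#' @return `sampled_curve` of kind `"plasma_parent"` on the same times.
#' @export
apply_metabolite_correction <- function(plasma_total, model) {
  stopifnot(inherits(plasma_total, "sampled_curve"))
  if (plasma_total$kind != "plasma_total") {
    stop("plasma curve must be of kind 'plasma_total'")
  }
  f <- predict_parent_fraction(model, plasma_total$times)
  sampled_curve(plasma_total$times, plasma_total$values * f,
                kind = "plasma_parent")
}
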