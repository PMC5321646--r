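#' Fit configuration
#'
#' Settings shared by the nonlinear fits: fixed blood volume fraction,
#' weighting scheme, parameter bounds, number of multistart restarts and the
#' RNG seed that makes the restarts reproducible.
#'
#' @param vB_fixed Fixed blood volume fraction (default 0.05).
#' @param weights `"uniform"` (default) or `"frame_duration"`. Uniform
#'   weighting matches a constant-SD noise model; frame-duration weighting
#'   up-weights long frames.
#' @param lower,upper Named bounds for `K1` and for the small rates
#'   (`k2`..`k6` share one bound pair).
#' @param multistart Number of seeded restarts (log-uniform over the bounds).
#' @param seed Integer seed for the restart draws.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(vB_fixed = 0.05,
                       weights = c("uniform", "frame_duration"),
                       lower = c(K1 = 0.01, k = 0.001),
                       upper = c(K1 = 5, k = 5),
                       multistart = 5, seed = 42L) {
  weights <- match.arg(weights)
  if (vB_fixed < 0 || vB_fixed > 1) stop("vB_fixed must lie in [0, 1]")
  if (multistart < 1) stop("multistart must be >= 1")
  structure(list(vB_fixed = vB_fixed, weights = weights,
                 lower = lower, upper = upper,
                 multistart = as.integer(multistart),
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Akaike information criterion for least-squares fits
#'
#' `AIC = n * log(rss / n) + 2 * k`, the least-squares form without
#' small-sample correction. Comparisons are always within one TAC, so any
#' additive constant cancels. A perfect (zero-RSS) fit returns `-Inf` with
#' attribute `perfect_fit = TRUE`.
#'
#' @param rss Residual sum of squares.
#' @param n_frames Number of fitted frames.
#' @param n_free Number of free parameters (must be < `n_frames`).
#' @return AIC value (scalar).
#' @export
aic_rss <- function(rss, n_frames, n_free) {
  if (rss < 0) stop("rss must be non-negative")
  if (n_free >= n_frames) stop("n_free must be smaller than n_frames")
  if (rss == 0) {
    out <- -Inf
    attr(out, "perfect_fit") <- TRUE
    return(out)
  }
  n_frames * log(rss / n_frames) + 2 * n_free
}

frame_weights <- function(config, schedule) {
  if (config$weights == "frame_duration") {
    schedule$durations / mean(schedule$durations)
  } else {
    rep(1, length(schedule$starts))
  }
}

# Draw multistart starting points: first a fixed default, then log-uniform
# draws over the box from a private RNG stream (the caller's RNG state is
# left untouched).
multistart_points <- function(lower, upper, n, seed, default) {
  pts <- list(pmin(pmax(default, lower), upper))
  if (n > 1) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    for (i in seq_len(n - 1)) {
      u <- stats::runif(length(lower))
      pts[[i + 1]] <- exp(log(lower) + u * (log(upper) - log(lower)))
    }
  }
  pts
}

#' Fit a plasma-input compartment model to a TAC
#'
#' Weighted nonlinear least squares for the 1TCM or 2TCM with fixed blood
#' volume fraction and fixed input delay. The objective is
#' `sum(w_i * (tac_i - model_i)^2)` over frame averages; optimization is
#' Levenberg-Marquardt within bounds, restarted from `config$multistart`
#' seeded log-uniform points, keeping the best.
#'
#' @param tac Measured tissue TAC (values at frame midpoints), a
#'   [sampled_curve()].
#' @param parent_plasma,whole_blood Input curves, [sampled_curve()].
#' @param schedule [frame_schedule()] matching the TAC.
#' @param model_kind `"1T"` or `"2T"`.
#' @param config [fit_config()].
#' @param delay Fixed input delay in minutes (from
#'   [estimate_blood_delay()]).
#' @return Object of class `pk_fit`: fitted `params` ([micro_params()]),
#'   `delay`, `rss`, `aic`, `macro` (VT, BPND), the fitted frame curve and
#'   bookkeeping (`n_frames`, `n_free`, `at_bounds`).
#' @export
fit_compartment_model <- function(tac, parent_plasma, whole_blood, schedule,
                                  model_kind = c("2T", "1T"),
                                  config = fit_config(), delay = 0) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(tac, "sampled_curve"),
            inherits(schedule, "frame_schedule"))
  y <- tac$values
  if (length(y) != length(schedule$starts)) {
    stop("TAC length must match the schedule")
  }
  ctx <- model_context(parent_plasma, whole_blood, schedule, delay)
  w <- frame_weights(config, schedule)
  sw <- sqrt(w)
  n_par <- if (model_kind == "1T") 2L else 4L
  lower <- c(config$lower[["K1"]], rep(config$lower[["k"]], n_par - 1L))
  upper <- c(config$upper[["K1"]], rep(config$upper[["k"]], n_par - 1L))

  par_to_micro <- function(p) {
    if (model_kind == "1T") {
      micro_params(p[1], p[2], vB = config$vB_fixed)
    } else {
      micro_params(p[1], p[2], p[3], p[4], vB = config$vB_fixed)
    }
  }
  resid_fun <- function(p) sw * (model_frames(par_to_micro(p), ctx) - y)

  default <- if (model_kind == "1T") c(0.5, 0.5) else c(0.5, 0.5, 0.2, 0.1)
  starts <- multistart_points(lower, upper, config$multistart, config$seed,
                              default)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(s, lower, upper, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) stop("fit failure: no restart converged")

  params <- par_to_micro(best$par)
  fitted <- model_frames(params, ctx)
  n <- length(y)
  at_bounds <- any(abs(best$par - lower) < 1e-9 | abs(best$par - upper) < 1e-9)
  structure(list(model_kind = paste0(model_kind, "CM"),
                 params = params, delay = delay,
                 rss = best$rss, n_frames = n, n_free = n_par,
                 aic = aic_rss(best$rss, n, n_par),
                 macro = macro_from_micro(params),
                 fitted = sampled_curve(schedule$mid_min, fitted, "tissue"),
                 at_bounds = at_bounds),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit %s> VT = %.4g, rss = %.4g, AIC = %.4g%s\n",
              x$model_kind, x$macro$VT, x$rss, x$aic,
              if (isTRUE(x$at_bounds)) " [at bounds]" else ""))
  invisible(x)
}

#' Estimate the blood delay from the whole-brain TAC
#'
#' Finds the input delay minimizing the whole-brain compartment-fit RSS
#' over a bounded search (default +/- 0.5 min): a coarse 0.1-min grid, a
#' 0.01-min refinement around its minimum, then a parabolic vertex through
#' the best three points. The returned delay is meant to be passed, fixed,
#' to every regional fit.
#'
#' @param whole_brain_tac Whole-brain TAC, a [sampled_curve()].
#' @param parent_plasma,whole_blood Input curves.
#' @param schedule [frame_schedule()].
#' @param config [fit_config()]; `multistart` is reduced internally for the
#'   grid stage.
#' @param model_kind Model used for the delay fits (default `"2T"`, the
#'   model that fits all regions).
#' @param bound Half-width of the search window in minutes.
#' @return Delay in minutes, with attribute `at_bound = TRUE` if the optimum
#'   sits on the search boundary.
#' @export
estimate_blood_delay <- function(whole_brain_tac, parent_plasma, whole_blood,
                                 schedule, config = fit_config(),
                                 model_kind = "2T", bound = 0.5) {
  cfg_grid <- config
  cfg_grid$multistart <- min(config$multistart, 2L)
  rss_at <- function(d) {
    fit_compartment_model(whole_brain_tac, parent_plasma, whole_blood,
                          schedule, model_kind, cfg_grid, delay = d)$rss
  }
  coarse <- seq(-bound, bound, by = 0.1)
  r1 <- vapply(coarse, rss_at, numeric(1))
  d0 <- coarse[which.min(r1)]
  fine <- seq(max(-bound, d0 - 0.1), min(bound, d0 + 0.1), by = 0.01)
  r2 <- vapply(fine, rss_at, numeric(1))
  i <- which.min(r2)
  d <- fine[i]
  at_bound <- abs(abs(d) - bound) < 1e-9
  if (i > 1 && i < length(fine)) {
    # parabolic vertex through the minimum and its two neighbours
    x <- fine[(i - 1):(i + 1)]
    y <- r2[(i - 1):(i + 1)]
    den <- (x[1] - x[2]) * (y[2] - y[3]) - (x[3] - x[2]) * (y[2] - y[1])
    if (is.finite(den) && abs(den) > 0) {
      v <- x[2] + 0.5 * ((x[1] - x[2])^2 * (y[2] - y[3]) -
                         (x[3] - x[2])^2 * (y[2] - y[1])) / den
      if (v >= x[1] && v <= x[3]) d <- v
    }
  }
  if (at_bound) warning("delay estimate at search bound")
  attr(d, "at_bound") <- at_bound
  d
}

#' Tally AIC model preference across subjects
#'
#' For each region, counts which of two paired fits (same TAC, same weights)
#' has the lower AIC and reports the percentage preferring each model.
#' Exact AIC ties go to the simpler (fewer-parameter) model.
#'
#' @param fits A data frame with columns `region`, `subject`, `model`, `aic`
#'   containing exactly two models fitted per (region, subject).
#' @return Data frame with one row per region: `n`, `pct_<model>` columns.
#' @export
model_preference <- function(fits) {
  req <- c("region", "subject", "model", "aic")
  if (!all(req %in% names(fits))) {
    stop("fits needs columns region, subject, model, aic")
  }
  models <- sort(unique(fits$model))
  if (length(models) != 2L) stop("exactly two models must be present")
  # simpler model = fewer free params if available, else first alphabetically
  simpler <- models[1]
  if ("n_free" %in% names(fits)) {
    nf <- tapply(fits$n_free, fits$model, unique)
    simpler <- names(nf)[which.min(unlist(nf))]
  }
  out <- lapply(split(fits, fits$region), function(df) {
    wide <- stats::reshape(df[c("subject", "model", "aic")],
                           idvar = "subject", timevar = "model",
                           direction = "wide")
    a <- wide[[paste0("aic.", models[1])]]
    b <- wide[[paste0("aic.", models[2])]]
    if (anyNA(a) || anyNA(b)) stop("mismatched pairs in region ", df$region[1])
    pref1 <- a < b | (a == b & simpler == models[1])
    data.frame(region = df$region[1], n = length(a),
               p1 = 100 * mean(pref1), p2 = 100 * mean(!pref1))
  })
  out <- do.call(rbind, out)
  names(out)[3:4] <- paste0("pct_", models)
  rownames(out) <- NULL
  out
}
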