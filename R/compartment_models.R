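#' Compartment-model rate constants
#'
#' Micro parameters of a serial plasma-input compartment model. The model
#' order is determined by which rates are present: a one-tissue model (1TCM)
#' has `K1, k2`; a two-tissue model (2TCM) adds the specific-binding exchange
#' `k3, k4`; the three-tissue generative model (3TCM) adds a slow
#' non-specific compartment `k5, k6`. In the 3TCM the specific (`k3/k4`) and
#' non-specific (`k5/k6`) compartments both exchange directly with the free
#' compartment (two parallel branches): this is the unique two-branch wiring
#' consistent with the total distribution volume
#' `VT = (K1/k2) * (1 + k3/k4 + k5/k6)`.
#'
#' @param K1 Delivery, mL cm^-3 min^-1.
#' @param k2,k3,k4,k5,k6 Rate constants, min^-1. Leave `NULL` for rates a
#'   lower-order model does not have.
#' @param vB Blood volume fraction in \[0, 1\]; the measured PET signal is
#'   `(1 - vB) * C_tissue + vB * C_wholeblood`.
#' @return Object of class `micro_params`.
#' @export
micro_params <- function(K1, k2, k3 = NULL, k4 = NULL, k5 = NULL, k6 = NULL,
                         vB = 0.05) {
  rates <- c(K1 = K1, k2 = k2,
             if (!is.null(k3)) c(k3 = k3), if (!is.null(k4)) c(k4 = k4),
             if (!is.null(k5)) c(k5 = k5), if (!is.null(k6)) c(k6 = k6))
  if (anyNA(rates) || any(!is.finite(rates))) stop("rates must be finite")
  if (any(rates < 0)) stop("rates must be non-negative")
  if (xor(is.null(k3), is.null(k4))) stop("k3 and k4 must come together")
  if (xor(is.null(k5), is.null(k6))) stop("k5 and k6 must come together")
  if (!is.null(k5) && is.null(k3)) stop("a 3T model needs k3, k4 present")
  if (vB < 0 || vB > 1) stop("vB must lie in [0, 1]")
  order <- if (!is.null(k5)) 3L else if (!is.null(k3)) 2L else 1L
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
                 vB = vB, order = order),
            class = "micro_params")
}

#' @export
print.micro_params <- function(x, ...) {
  r <- unlist(x[c("K1", "k2", "k3", "k4", "k5", "k6")])
  cat(sprintf("<micro_params %dT> %s; vB = %g\n", x$order,
              paste(names(r), signif(r, 4), sep = " = ", collapse = ", "),
              x$vB))
  invisible(x)
}

# Impulse response h(t) = sum phi_i exp(-theta_i t) of the tissue system,
# such that C_T(t) = (Cp %conv% h)(t). 1T and 2T use closed forms; 3T uses
# the eigendecomposition of the rate matrix. Near-degenerate eigenvalues are
# handled by a tiny symmetric perturbation of k3/k5 (the limiting t*exp term
# is approximated to well below solver tolerance).
tissue_impulse <- function(p) {
  if (p$order == 1L) {
    return(list(theta = p$k2, phi = p$K1))
  }
  if (p$order == 2L) {
    s <- p$k2 + p$k3 + p$k4
    disc <- sqrt(max(s^2 - 4 * p$k2 * p$k4, 0))
    th1 <- (s + disc) / 2
    th2 <- (s - disc) / 2
    if (disc < 1e-9) {
      # degenerate pair: perturb within solver tolerance
      th1 <- th1 + 5e-10
      th2 <- th2 - 5e-10
      disc <- th1 - th2
    }
    ph1 <- p$K1 * (th1 - p$k3 - p$k4) / disc
    ph2 <- p$K1 * (p$k3 + p$k4 - th2) / disc
    return(list(theta = c(th1, th2), phi = c(ph1, ph2)))
  }
  imp <- function(k3, k5) {
    A <- matrix(c(-(p$k2 + k3 + k5), p$k4, p$k6,
                  k3, -p$k4, 0,
                  k5, 0, -p$k6), nrow = 3, byrow = TRUE)
    e <- eigen(A)
    b <- c(p$K1, 0, 0)
    w <- solve(e$vectors, b)
    phi <- as.numeric(colSums(e$vectors) * w)
    list(theta = -Re(e$values), phi = Re(phi))
  }
  r <- imp(p$k3, p$k5)
  if (min(abs(diff(sort(r$theta)))) < 1e-8) {
    r <- imp(p$k3 * (1 + 1e-7) + 1e-10, p$k5 * (1 - 1e-7))
  }
  r
}

# Fine-grid modeling context shared by the fitting routines: input curves
# interpolated onto the internal grid plus the frame-averaging matrix.
model_context <- function(parent_plasma, whole_blood, schedule,
                          delay = 0, dt_s = 0.5) {
  t_fine <- fine_grid(schedule, dt_s)
  list(t_fine = t_fine,
       dt = dt_s / 60,
       cp = evaluate_curve(parent_plasma, t_fine, delay),
       cb = if (is.null(whole_blood)) numeric(length(t_fine))
            else evaluate_curve(whole_blood, t_fine, delay),
       W = frame_average_matrix(schedule, dt_s),
       schedule = schedule)
}

# Frame-averaged model PET values for micro parameters p within a context.
model_frames <- function(p, ctx) {
  h <- tissue_impulse(p)
  ct <- numeric(length(ctx$t_fine))
  for (i in seq_along(h$theta)) {
    ct <- ct + h$phi[i] * conv_exp(ctx$cp, ctx$dt, h$theta[i])
  }
  pet <- (1 - p$vB) * ct + p$vB * ctx$cb
  frame_average(pet, ctx$W)
}

#' Model time-activity curve for a compartment configuration
#'
#' Generates the frame-averaged tissue TAC for rate constants `params`
#' driven by a metabolite-corrected plasma input, with the blood volume
#' contribution `vB * C_wholeblood` added before frame averaging. The tissue
#' response is computed by exact convolution of the (piecewise-linear) input
#' with the model's multi-exponential impulse response on an internal 0.5-s
#' grid; frame values are frame averages, not midpoint samples.
#'
#' @param params [micro_params()].
#' @param parent_plasma Parent-plasma input, a [sampled_curve()].
#' @param whole_blood Whole-blood curve, a [sampled_curve()], or `NULL`
#'   (treated as zero; only sensible with `vB = 0`).
#' @param schedule [frame_schedule()].
#' @param delay Input delay in minutes; the inputs are shifted later by this
#'   amount before convolution.
#' @return `sampled_curve` of kind `"tissue"`, sampled at frame midpoints,
#'   with the schedule attached as attribute `"schedule"`.
#' @export
model_tac <- function(params, parent_plasma, whole_blood, schedule,
                      delay = 0) {
  stopifnot(inherits(params, "micro_params"),
            inherits(schedule, "frame_schedule"))
  ctx <- model_context(parent_plasma, whole_blood, schedule, delay)
  vals <- model_frames(params, ctx)
  out <- sampled_curve(schedule$mid_min, vals, kind = "tissue")
  attr(out, "schedule") <- schedule
  out
}

#' Macro parameters from micro parameters
#'
#' Total distribution volume `VT = (K1/k2) * (1 + k3/k4 + k5/k6)` (absent
#' branches contribute zero) and the non-displaceable binding potential
#' `BPND = k3/k4` when the specific compartment is present.
#'
#' @param params [micro_params()].
#' @return List with `VT` and (when defined) `BPND`.
#' @export
macro_from_micro <- function(params) {
  stopifnot(inherits(params, "micro_params"))
  if (params$k2 <= 0) stop("k2 must be positive for VT")
  spec <- 0
  bp <- NULL
  if (!is.null(params$k3)) {
    if (params$k4 <= 0) stop("k4 must be positive when k3 is present")
    bp <- params$k3 / params$k4
    spec <- bp
  }
  nonspec <- 0
  if (!is.null(params$k5)) {
    if (params$k6 <= 0) stop("k6 must be positive when k5 is present")
    nonspec <- params$k5 / params$k6
  }
  list(VT = (params$K1 / params$k2) * (1 + spec + nonspec), BPND = bp)
}

#' Indirect binding potential from distribution volumes
#'
#' `DVR - 1 = VT / VT_reference - 1`, the plasma-input route to BPND via a
#' reference region's distribution volume.
#'
#' @param VT Target-region distribution volume(s).
#' @param VT_reference Reference-region distribution volume (> 0).
#' @return Numeric of the same length as `VT`.
#' @export
dvr_minus_one <- function(VT, VT_reference) {
  if (!is.finite(VT_reference) || VT_reference <= 0) {
    stop("VT_reference must be positive")
  }
  VT / VT_reference - 1
}
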