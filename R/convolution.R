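# Exact convolution of a piecewise-linear signal with a decaying
# exponential on a uniform grid.
#
# Given x sampled at constant step dt (minutes) and treated as
# piecewise-linear, returns y_n = integral_0^{t_n} x(s) exp(-beta (t_n - s)) ds.
# The per-step increment has a closed form, so the whole convolution is a
# first-order recursion evaluated by stats::filter (O(n), C speed). This is
# the workhorse behind every compartment model, spectral basis function and
# reference-model basis in the package.
conv_exp <- function(x, dt, beta) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  if (beta < 0) stop("beta must be non-negative")
  bd <- beta * dt
  if (bd < 1e-9) {
    # beta -> 0 limit: running trapezoidal integral
    inc <- c(0, (x[-n] + x[-1L]) * dt / 2)
    return(cumsum(inc))
  }
  E <- exp(-bd)
  if (bd > 1e-4) {
    B <- 1 / beta - (1 - E) / (beta^2 * dt)
    A <- (1 - E) / beta - B
  } else {
    # series forms, avoiding catastrophic cancellation at tiny beta*dt
    B <- dt * (1 / 2 - bd / 6 + bd^2 / 24)
    A <- dt * (1 / 2 - bd / 3 + bd^2 / 8)
  }
  z <- c(0, A * x[-n] + B * x[-1L])
  as.numeric(stats::filter(z, E, method = "recursive"))
}
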