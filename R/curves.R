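#' Sampled concentration curve
#'
#' A time-stamped concentration series: whole blood, total plasma, parent
#' (metabolite-corrected) plasma, a tissue time-activity curve (TAC), or a
#' dimensionless fraction curve. Times are minutes post-injection and must be
#' strictly increasing; concentrations are kBq/mL (fractions are unitless and
#' must lie in \[0, 1\]).
#'
#' @param times Numeric vector of sample times in minutes, strictly
#'   increasing, non-negative.
#' @param values Numeric vector of the same length; activity concentration
#'   (kBq/mL) or fraction.
#' @param kind One of `"whole_blood"`, `"plasma_total"`, `"plasma_parent"`,
#'   `"tissue"`, `"fraction"`.
#' @return An object of class `sampled_curve`.
#' @export
sampled_curve <- function(times, values,
                          kind = c("tissue", "whole_blood", "plasma_total",
                                   "plasma_parent", "fraction")) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) == 0L) stop("empty curve: no samples")
  if (length(times) != length(values)) {
    stop("times and values must have the same length")
  }
  if (anyNA(times) || anyNA(values) || any(!is.finite(times)) ||
      any(!is.finite(values))) {
    stop("times and values must be finite")
  }
  if (any(times < 0)) stop("times must be non-negative")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (kind == "fraction" && (any(values < -1e-12) || any(values > 1 + 1e-12))) {
    stop("fraction-kind values must lie in [0, 1]")
  }
  structure(list(times = times, values = values, kind = kind),
            class = "sampled_curve")
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("<sampled_curve [%s]> %d samples over [%.3g, %.3g] min\n",
              x$kind, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Evaluate a sampled curve at arbitrary times
#'
#' Piecewise-linear interpolation with the interpolation contract used by all
#' convolution integrals in the package: the curve is 0 before its first
#' sample (pre-injection) and holds its last value after the final sample.
#' A positive `delay` shifts the curve later in time, i.e. the curve is
#' evaluated at `t - delay`.
#'
#' @param curve A [sampled_curve()].
#' @param t Numeric vector of query times in minutes.
#' @param delay Delay in minutes (default 0).
#' @return Numeric vector of interpolated values.
#' @export
evaluate_curve <- function(curve, t, delay = 0) {
  stopifnot(inherits(curve, "sampled_curve"))
  if (!is.finite(delay)) stop("delay must be finite")
  if (anyNA(t) || any(!is.finite(t))) stop("query times must be finite")
  tq <- t - delay
  out <- stats::approx(curve$times, curve$values, xout = tq,
                       method = "linear", yleft = 0,
                       yright = curve$values[length(curve$values)])$y
  out
}

#' Read/write sampled curves as CSV/TSV
#'
#' The on-disk format has header columns `time_min`, `value`, `kind`.
#' The separator is inferred from the file extension (`.tsv` uses tab).
#'
#' @param path File path.
#' @return [read_curve()] returns a `sampled_curve`.
#' @export
read_curve <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("time_min", "value", "kind")
  if (!all(req %in% names(df))) {
    stop("curve file must have columns time_min, value, kind")
  }
  sampled_curve(df$time_min, df$value, kind = df$kind[1])
}

#' @param curve A `sampled_curve` to write.
#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sampled_curve"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(time_min = curve$times, value = curve$values,
                   kind = curve$kind)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PMOD-style .tac multi-column table
#'
#' Whitespace- or tab-separated text with a header line; the first column is
#' time, each subsequent column a region TAC. Time units of seconds are
#' converted to minutes when `time_unit = "seconds"`.
#'
#' @param path File path.
#' @param time_unit `"minutes"` (default) or `"seconds"`.
#' @return Named list of `sampled_curve` objects of kind `"tissue"`.
#' @export
read_tac_table <- function(path, time_unit = c("minutes", "seconds")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stop(".tac table needs a time column plus >=1 region")
  tt <- df[[1L]]
  if (time_unit == "seconds") tt <- tt / 60
  out <- lapply(df[-1L], function(v) sampled_curve(tt, v, kind = "tissue"))
  names(out) <- names(df)[-1L]
  out
}
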