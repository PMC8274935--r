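#' Tabulated voltage-clamp dataset
#'
#' A simple x-y container for protocol outputs and fitting targets: `x` is
#' the swept quantity (a voltage in mV, an interval in ms, a frequency in Hz
#' or a concentration in M depending on the protocol), `y` the measured
#' summary (a normalized fraction, or a time in ms for `t_half` data).
#'
#' @param x swept values.
#' @param y measured values, same length as `x`.
#' @param weight optional per-point weights (default 1).
#' @param protocol protocol tag, one of
#'   `"availability"`, `"activation"`, `"t_half"`, `"tau_m"`,
#'   `"tonic_block"`, `"udb_dose"`, `"udb_freq"`, `"recovery"`.
#' @param x_units,y_units unit strings for documentation/round-tripping.
#' @param provenance free-text provenance (generator, seed, truth preset).
#' @return An object of class `clamp_dataset` (a list).
#' @export
clamp_dataset <- function(x, y, weight = NULL,
                          protocol = c("availability", "activation", "t_half",
                                       "tau_m", "tonic_block", "udb_dose",
                                       "udb_freq", "recovery"),
                          x_units = "", y_units = "", provenance = "") {
  protocol <- match.arg(protocol)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (is.null(weight)) weight <- rep(1, length(x))
  stopifnot(length(weight) == length(x), all(weight >= 0))
  if (protocol %in% c("availability", "activation", "tonic_block",
                      "udb_dose", "udb_freq", "recovery") &&
      any(y < -1e-9 | y > 1 + 1e-9))
    stop("fraction-valued protocol '", protocol, "' requires y in [0, 1]")
  structure(list(x = x, y = y, weight = weight, protocol = protocol,
                 x_units = x_units, y_units = y_units,
                 provenance = provenance),
            class = "clamp_dataset")
}

#' @export
print.clamp_dataset <- function(x, ...) {
  cat(sprintf("<clamp_dataset> %s: %d points, x in [%g, %g] %s\n",
              x$protocol, length(x$x), min(x$x), max(x$x), x$x_units))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Mean squared model-data error
#'
#' `sse(y, x) = (1/n) * sum((y_i - x_i)^2)` -- note that despite the
#' conventional name this summary is a *mean* of squared differences, so it
#' is comparable across datasets of different size.
#'
#' @param model_y model outputs.
#' @param data_y observed values, same length.
#' @param weight optional per-point weights (normalized to mean 1).
#' @return nonnegative scalar.
#' @export
sse <- function(model_y, data_y, weight = NULL) {
  if (length(model_y) != length(data_y))
    stop("sse: length mismatch (", length(model_y), " vs ",
         length(data_y), ")")
  d2 <- (model_y - data_y)^2
  if (is.null(weight)) return(mean(d2))
  stopifnot(length(weight) == length(d2))
  sum(weight * d2) / sum(weight)
}
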