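#' Piecewise-constant voltage-clamp waveforms
#'
#' All waveforms in the package are represented as an ordered list of
#' constant-voltage segments.  Each segment carries its command voltage
#' (mV), duration (ms), a per-segment output sampling interval (ms), and an
#' optional label used by protocol code to locate test pulses.  Integration
#' restarts at every segment boundary, so voltage discontinuities are handled
#' exactly.
#'
#' @param V segment voltages (mV).
#' @param dur segment durations (ms), all > 0.
#' @param sample_dt per-segment output sampling interval (ms); recycled.
#' @param label optional character labels; recycled.
#' @return An object of class `voltage_waveform` wrapping a data frame with
#'   columns `V`, `dur`, `sample_dt`, `label`.
#' @examples
#' w <- step_waveform(V = c(-100, -20, -100), dur = c(50, 20, 50))
#' waveform_duration(w)
#' @export
step_waveform <- function(V, dur, sample_dt = 1, label = "") {
  stopifnot(is.numeric(V), is.numeric(dur), length(V) == length(dur))
  if (any(!is.finite(V)) || any(!is.finite(dur)) || any(dur <= 0))
    stop("segment voltages must be finite and durations > 0")
  seg <- data.frame(V = V, dur = dur,
                    sample_dt = rep_len(sample_dt, length(V)),
                    label = rep_len(as.character(label), length(V)),
                    stringsAsFactors = FALSE)
  structure(list(segments = seg), class = "voltage_waveform")
}

#' @rdname step_waveform
#' @param w a `voltage_waveform`.
#' @export
waveform_duration <- function(w) sum(w$segments$dur)

#' @rdname step_waveform
#' @export
constant_hold <- function(V, dur, sample_dt = dur / 100) {
  step_waveform(V, dur, sample_dt = sample_dt, label = "hold")
}

#' Square-wave action-potential clamp
#'
#' A periodic two-level waveform alternating between a plateau potential
#' `V_AP` (held for `APD` ms) and a diastolic potential `V_DI` (held for
#' `DI` ms).  Cycle `k` starts (upstroke) at `t_k = (k - 1) * (APD + DI)`.
#'
#' @param V_AP plateau potential (mV); default 20.
#' @param V_DI diastolic potential (mV); default -85.
#' @param APD action-potential duration (ms), > 0.
#' @param DI diastolic interval (ms), > 0.
#' @param n_cycles number of pacing cycles.
#' @param sample_dt output sampling interval (ms).
#' @return a `voltage_waveform` whose segments are labelled `"ap"`/`"di"`.
#' @export
square_wave_clamp <- function(V_AP = 20, V_DI = -85, APD, DI, n_cycles = 1,
                              sample_dt = 1) {
  stopifnot(APD > 0, DI > 0, n_cycles >= 1)
  if (V_AP <= V_DI) stop("require V_AP > V_DI")
  step_waveform(V = rep(c(V_AP, V_DI), n_cycles),
                dur = rep(c(APD, DI), n_cycles),
                sample_dt = sample_dt,
                label = rep(c("ap", "di"), n_cycles))
}

#' Discretize a sampled voltage trace into a piecewise-constant waveform
#'
#' Arbitrary (e.g. ramped) waveforms are reduced to fine piecewise-constant
#' staircases: segment `i` holds the midpoint voltage
#' `(V[i] + V[i+1]) / 2` over `[t[i], t[i+1])`.  With the default step used
#' by [gen_ap_waveform()] the staircase error is negligible relative to the
#' model time constants.
#'
#' @param t strictly increasing sample times (ms).
#' @param V voltages at `t` (mV).
#' @param sample_dt output sampling interval (ms).
#' @return a `voltage_waveform`.
#' @export
sampled_waveform <- function(t, V, sample_dt = 1) {
  stopifnot(length(t) == length(V), length(t) >= 2, all(diff(t) > 0))
  n <- length(t)
  step_waveform(V = (V[-n] + V[-1]) / 2, dur = diff(t),
                sample_dt = sample_dt, label = "sampled")
}

#' @export
print.voltage_waveform <- function(x, ...) {
  s <- x$segments
  cat(sprintf("<voltage_waveform> %d segments, %.6g ms total\n",
              nrow(s), sum(s$dur)))
  if (nrow(s) <= 12) print(s) else {
    print(utils::head(s, 4))
    cat("  ... (", nrow(s) - 4, " more segments)\n", sep = "")
  }
  invisible(x)
}

#' Voltage at arbitrary times
#'
#' @param w a `voltage_waveform`.
#' @param t times (ms) within the waveform span; the voltage at a segment
#'   boundary is that of the segment starting there (right-continuous).
#' @return voltages (mV).
#' @export
voltage_at <- function(w, t) {
  edges <- c(0, cumsum(w$segments$dur))
  if (any(t < 0 | t > edges[length(edges)] + 1e-9))
    stop("time outside waveform span")
  idx <- pmin(findInterval(t, edges, rightmost.closed = TRUE),
              nrow(w$segments))
  w$segments$V[idx]
}
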