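#' Action-potential-duration restitution curves
#'
#' A restitution curve maps pacing cycle length to steady-state action
#' potential duration, `APD = f(BCL)`, with `DI = BCL - APD`.  Three
#' realizations are supported:
#' \describe{
#'   \item{`exponential`}{`f(BCL) = apd_max * (1 - a * exp(-BCL / tau_r))`,
#'     with analytic derivative.}
#'   \item{`flat`}{constant APD (zero slope).}
#'   \item{`tabulated`}{monotone piecewise-cubic (Fritsch-Carlson)
#'     interpolation of `(bcl, apd)` points; the derivative is taken from
#'     the interpolant.}
#' }
#' Validity (`0 < f(BCL) < BCL`, `f` nondecreasing) is checked on a grid
#' over the stated domain.
#'
#' @param form one of `"exponential"`, `"flat"`, `"tabulated"`.
#' @param apd_max,a,tau_r exponential-form parameters (ms, -, ms).
#' @param apd constant APD for the flat form (ms).
#' @param bcl,apd_tab knots for the tabulated form (ms).
#' @param domain BCL domain `c(lo, hi)` (ms).
#' @return An object of class `restitution_curve` with fields `f` and `df`
#'   (functions of BCL), `domain`, `form`, `params`.
#' @examples
#' rc <- restitution_curve("exponential", apd_max = 320, a = 1, tau_r = 200)
#' apd_at(rc, 750)
#' apd_slope(rc, 750)
#' @export
restitution_curve <- function(form = c("exponential", "flat", "tabulated"),
                              apd_max = 320, a = 1, tau_r = 200,
                              apd = 250, bcl = NULL, apd_tab = NULL,
                              domain = c(300, 1000)) {
  form <- match.arg(form)
  stopifnot(length(domain) == 2, domain[1] > 0, domain[2] > domain[1])
  if (form == "exponential") {
    stopifnot(apd_max > 0, tau_r > 0, a >= 0)
    f <- function(BCL) apd_max * (1 - a * exp(-BCL / tau_r))
    df <- function(BCL) apd_max * a / tau_r * exp(-BCL / tau_r)
    params <- list(apd_max = apd_max, a = a, tau_r = tau_r)
  } else if (form == "flat") {
    stopifnot(apd > 0)
    f <- function(BCL) rep_len(apd, length(BCL))
    df <- function(BCL) rep_len(0, length(BCL))
    params <- list(apd = apd)
  } else {
    stopifnot(!is.null(bcl), !is.null(apd_tab),
              length(bcl) == length(apd_tab), length(bcl) >= 3,
              all(diff(bcl) > 0))
    if (any(diff(apd_tab) < 0)) stop("tabulated APD must be nondecreasing")
    sf <- stats::splinefun(bcl, apd_tab, method = "monoH.FC")
    f <- function(BCL) sf(BCL)
    df <- function(BCL) sf(BCL, deriv = 1)
    params <- list(bcl = bcl, apd = apd_tab)
    domain <- c(max(domain[1], min(bcl)), min(domain[2], max(bcl)))
  }
  rc <- structure(list(f = f, df = df, domain = domain, form = form,
                       params = params),
                  class = "restitution_curve")
  g <- seq(domain[1], domain[2], length.out = 201)
  fv <- f(g)
  if (any(fv <= 0) || any(fv >= g))
    stop("invalid restitution curve: need 0 < f(BCL) < BCL on the domain")
  if (any(diff(fv) < -1e-9)) stop("restitution curve must be nondecreasing")
  rc
}

#' @rdname restitution_curve
#' @param rc a `restitution_curve`.
#' @param BCL cycle lengths (ms), inside `rc$domain`.
#' @export
apd_at <- function(rc, BCL) {
  check_bcl(rc, BCL)
  rc$f(BCL)
}

#' @rdname restitution_curve
#' @export
apd_slope <- function(rc, BCL) {
  check_bcl(rc, BCL)
  rc$df(BCL)
}

check_bcl <- function(rc, BCL) {
  if (any(BCL < rc$domain[1] - 1e-9 | BCL > rc$domain[2] + 1e-9))
    stop(sprintf("BCL outside restitution domain [%g, %g] ms",
                 rc$domain[1], rc$domain[2]))
  invisible(TRUE)
}

#' @export
print.restitution_curve <- function(x, ...) {
  cat(sprintf("<restitution_curve> form = %s, domain = [%g, %g] ms\n",
              x$form, x$domain[1], x$domain[2]))
  invisible(x)
}
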