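# Binary-choice dynamics of smoking prevalence.
#
# dx/dt = b [ (1 - x) x^a u_x  -  x (1 - x)^a (1 - u_x) ]
#
# Non-smokers adopt at a rate proportional to the total utility from smoking
# (social utility x, weighted by the conformity exponent a, times individual
# utility u_x); smokers quit symmetrically under the complementary utilities.

#' Instantaneous rate of change of smoking prevalence
#'
#' @param x Smoking prevalence, fraction in `[0, 1]` (vectorized).
#' @param u Individual utility from smoking in `[0, 1]`.
#' @param a Relative conformity exponent, `a >= 0`; `a > 1` weighs social
#'   utility more heavily (collectivistic), `a < 1` less (individualistic).
#' @param b Timescale constant, `b > 0`, units 1/years.
#' @return dx/dt in 1/years.
#' @export
smoking_rate <- function(x, u, a, b) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("prevalence x must lie in [0, 1]")
  }
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    stop("utility u must lie in [0, 1]")
  }
  if (!is.finite(a) || a < 0) stop("conformity exponent a must be >= 0")
  if (!is.finite(b) || b <= 0) stop("timescale b must be > 0")
  smoking_rate_unsafe(x, u, a, b)
}

# Internal rate law without domain checks; clamps x into [0,1] so that solver
# trial states a rounding error outside the simplex cannot produce NaN from
# fractional powers (x^a at x = 0 with a < 1 is taken as its continuous
# extension, 0).
smoking_rate_unsafe <- function(x, u, a, b) {
  x <- pmin(pmax(x, 0), 1)
  b * ((1 - x) * x^a * u - x * (1 - x)^a * (1 - u))
}

#' Simulate a prevalence trajectory
#'
#' Integrates the rate law from the initial condition `x(t0) = x0` under a
#' time-varying individual utility, using an adaptive Dormand-Prince
#' Runge-Kutta 4(5) solver with dense output at the requested years
#' (relative tolerance 1e-8, absolute 1e-10 by default). If the solution
#' strays outside `[0, 1]` by more than `1e-9` the integration is repeated
#' with tolerances tightened 100-fold; values inside that band are clipped
#' for reporting only.
#'
#' @param a,b Conformity exponent and timescale (see [smoking_rate()]).
#' @param x0 Initial prevalence fraction in `[0, 1]`.
#' @param t0 Initial year; must not exceed the first output year.
#' @param spec A [utility_spec()].
#' @param years Numeric vector of output years (increasing).
#' @param curve A [knowledge_curve()] (required for the discounted form).
#' @param rtol,atol Solver tolerances.
#' @return Data frame with columns `year` and `x` (class
#'   `prevalence_trajectory`).
#' @export
simulate_prevalence <- function(a, b, x0, t0, spec, years, curve = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(is.finite(x0), x0 >= 0, x0 <= 1, all(diff(years) > 0))
  if (t0 > years[1]) stop("t0 must not exceed the first output year")
  if (spec$form == "discounted" && is.null(curve)) {
    stop("the discounted form needs a knowledge curve")
  }
  sol <- integrate_prevalence(a, b, x0, t0, spec, curve, years, rtol, atol)
  if (any(sol < -1e-9 | sol > 1 + 1e-9)) {
    sol <- integrate_prevalence(a, b, x0, t0, spec, curve, years,
                                rtol / 100, atol / 100)
    if (any(sol < -1e-6 | sol > 1 + 1e-6)) {
      stop("integration error: trajectory escaped [0, 1] beyond tolerance")
    }
  }
  structure(data.frame(year = years, x = pmin(pmax(sol, 0), 1)),
            class = c("prevalence_trajectory", "data.frame"))
}

# Integration via deSolve's ode45 with the rate law compiled in src/; the
# knowledge curve enters as a linearly interpolated forcing series.
integrate_prevalence <- function(a, b, x0, t0, spec, curve, years, rtol,
                                 atol) {
  times <- if (t0 < years[1]) c(t0, years) else years
  if (length(times) == 1L) return(x0)  # x(t0) = x0, nothing to integrate

  form_code <- match(spec$form, c("discounted", "step", "constant"))
  pv <- c(a, b, form_code, 0, 0, 0, 0, 0)
  forcmat <- cbind(c(times[1] - 1, times[length(times)] + 1), c(0, 0))
  if (spec$form == "discounted") {
    pv[4:5] <- c(spec$u0, spec$u_inf)
    # log(delta); delta = 0 is represented by a log small enough that
    # exp(n log delta) underflows for any n >= 1 while 0^0 := 1 survives
    pv[6] <- if (spec$delta == 0) -700 else log(spec$delta)
    forcmat <- cbind(curve$years, curve$cumulative)
    if (times[1] < curve$years[1]) {
      # preserve the "no knowledge before the first sample" rule: a
      # numerically vertical ramp just before the first sample year
      forcmat <- rbind(c(times[1] - 1, 0),
                       c(curve$years[1] - 1e-7, 0),
                       forcmat)
    }
  } else if (spec$form == "step") {
    pv[c(4, 5, 7)] <- c(spec$u0, spec$u_inf, spec$t_star)
  } else {
    pv[8] <- spec$u_const
  }

  out <- deSolve::ode(y = c(x = x0), times = times, func = "sd_derivs",
                      parms = pv, dllname = "smokedyn",
                      initfunc = "sd_initmod", initforc = "sd_initforc",
                      forcings = forcmat,
                      fcontrol = list(method = "linear", rule = 2),
                      method = "ode45", rtol = rtol, atol = atol)
  if (nrow(out) < length(times) || anyNA(out[, 2])) {
    stop(sprintf("integration error: solver stopped at t = %g (a=%g, b=%g, x0=%g)",
                 out[nrow(out), 1], a, b, x0))
  }
  out[match(years, out[, 1]), 2]
}

#' @export
print.prevalence_trajectory <- function(x, ...) {
  cat(sprintf("<prevalence_trajectory> %d years (%g-%g), x in [%.4f, %.4f]\n",
              nrow(x), min(x$year), max(x$year), min(x$x), max(x$x)))
  invisible(x)
}
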