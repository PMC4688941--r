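# Estimation of historical smoking prevalence from cigarette consumption.
#
# Survey prevalence is sparse (roughly 1960 onward); per-capita cigarette
# consumption reaches back to the early 1900s. Assuming x(t) = C c(t) + B,
# an OLS fit on the overlap years gives (C_hat, B_hat), and
# x_hat(t) = C_hat c(t) + B_hat extends the prevalence record to every
# consumption year.

#' Fit the per-country affine consumption-to-prevalence map
#'
#' Ordinary least squares of survey prevalence on consumption over all years
#' where both are recorded, optionally after removing analyst-listed outlier
#' survey years.
#'
#' @param series A [country_series()].
#' @param exclude_years Integer vector of survey years to drop before the
#'   regression (e.g. a screened outlier).
#' @return An object of class `linear_map` with fields `C_hat`, `B_hat`,
#'   `r2`, `p` (two-sided slope p-value), `n_obs`, `years`, `country_id`.
#' @export
fit_linear_map <- function(series, exclude_years = integer()) {
  stopifnot(inherits(series, "country_series"))
  prev <- series$prevalence
  prev <- prev[!prev$year %in% exclude_years, ]
  overlap <- merge(prev, series$consumption, by = "year",
                   suffixes = c("_x", "_c"))
  if (nrow(overlap) < 2L) {
    stop(sprintf("country %d: fewer than 2 overlapping years (%d)",
                 series$country_id, nrow(overlap)))
  }
  if (stats::var(overlap$value_c) == 0) {
    stop(sprintf("country %d: consumption has zero variance over the overlap",
                 series$country_id))
  }
  fit <- stats::lm(value_x ~ value_c, data = overlap)
  # exact affine data (the noise-free limit) is a designed use case; silence
  # summary.lm's "essentially perfect fit" notice
  sm <- suppressWarnings(summary(fit))
  structure(list(country_id = series$country_id,
                 C_hat = unname(stats::coef(fit)[2]),
                 B_hat = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 p = unname(sm$coefficients[2, 4]),
                 n_obs = nrow(overlap),
                 years = overlap$year,
                 excluded = sort(as.integer(exclude_years))),
            class = "linear_map")
}

#' @export
print.linear_map <- function(x, ...) {
  cat(sprintf("<linear_map> country %d: x_hat = %.4g c + %.4g  (R2=%.3f, p=%.3g, n=%d)\n",
              x$country_id, x$C_hat, x$B_hat, x$r2, x$p, x$n_obs))
  invisible(x)
}

#' Estimate prevalence from consumption via a fitted map
#'
#' Applies x_hat(t) = C_hat c(t) + B_hat at every consumption year. Values
#' are deliberately not clamped to `[0, 1]`: the raw affine estimates are the
#' calibration target and clamping would bias the fit errors.
#'
#' @param series A [country_series()] with consumption data.
#' @param map A [fit_linear_map()] result.
#' @return Data frame with columns `year`, `x_hat` (class
#'   `prevalence_estimate`), carrying the country id as an attribute.
#' @export
estimate_prevalence <- function(series, map) {
  stopifnot(inherits(series, "country_series"), inherits(map, "linear_map"))
  out <- data.frame(year = series$consumption$year,
                    x_hat = map$C_hat * series$consumption$value + map$B_hat)
  attr(out, "country_id") <- series$country_id
  class(out) <- c("prevalence_estimate", "data.frame")
  out
}

# Two-sided single-outlier Grubbs critical value at significance alpha for
# sample size n: G = ((n-1)/sqrt(n)) sqrt(t^2 / (n - 2 + t^2)) with t the
# upper alpha/(2n) quantile of Student's t on n-2 df.
grubbs_critical <- function(n, alpha) {
  tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

# p-value of an observed Grubbs statistic G (inverse of the above).
grubbs_p_value <- function(G, n) {
  t2 <- (n * (n - 2) * G^2) / ((n - 1)^2 - n * G^2)
  if (!is.finite(t2) || t2 < 0) return(0)
  min(1, 2 * n * stats::pt(sqrt(t2), df = n - 2, lower.tail = FALSE))
}

#' Screen survey years for outliers with the Grubbs test
#'
#' Applies the two-sided single-outlier Grubbs test to the ratios
#' x(t) / x_hat(t) over the overlap years. At most one year (the maximum
#' studentized deviation) is flagged per call; iterate after removal to
#' screen further. Zero variance in the ratios flags nothing.
#'
#' @param series A [country_series()].
#' @param map A [fit_linear_map()] result for the same country.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns `year`, `ratio`, `G`, `p` for the flagged
#'   year, or zero rows if none is significant.
#' @export
grubbs_screen <- function(series, map, alpha = 0.05) {
  stopifnot(inherits(series, "country_series"), inherits(map, "linear_map"))
  overlap <- merge(series$prevalence, series$consumption, by = "year",
                   suffixes = c("_x", "_c"))
  n <- nrow(overlap)
  if (n < 3L) stop("Grubbs screening needs at least 3 overlapping years")
  x_hat <- map$C_hat * overlap$value_c + map$B_hat
  ratio <- overlap$value_x / x_hat
  s <- stats::sd(ratio)
  empty <- data.frame(year = integer(), ratio = numeric(), G = numeric(),
                      p = numeric())
  if (s == 0) return(empty)
  dev <- abs(ratio - mean(ratio)) / s
  i <- which.max(dev)
  G <- dev[i]
  if (G > grubbs_critical(n, alpha)) {
    data.frame(year = overlap$year[i], ratio = ratio[i], G = G,
               p = grubbs_p_value(G, n))
  } else {
    empty
  }
}

#' Apply the data-quality inclusion filter
#'
#' Keeps countries whose affine map satisfies R2 >= `r2_min`, slope p-value
#' < `p_max`, and number of overlap years >= `n_min` (defaults reproduce the
#' seven-country OECD selection).
#'
#' @param maps List of [fit_linear_map()] results.
#' @param r2_min,p_max,n_min Thresholds.
#' @return Integer vector of selected country ids (possibly empty, with a
#'   warning).
#' @export
select_countries <- function(maps, r2_min = 0.7, p_max = 0.001, n_min = 15) {
  keep <- vapply(maps, function(m) {
    m$r2 >= r2_min && m$p < p_max && m$n_obs >= n_min
  }, logical(1))
  ids <- vapply(maps[keep], function(m) as.integer(m$country_id), integer(1))
  if (length(ids) == 0L) warning("no country passes the inclusion filter")
  sort(unname(ids))
}

#' Summarise affine maps as a table
#'
#' @param maps List of [fit_linear_map()] results.
#' @param r2_min,p_max,n_min Thresholds passed to [select_countries()].
#' @return Data frame with one row per country: `country_id`, `C_hat`,
#'   `B_hat`, `r2`, `p`, `n_obs`, `included`.
#' @export
map_table <- function(maps, r2_min = 0.7, p_max = 0.001, n_min = 15) {
  sel <- suppressWarnings(select_countries(maps, r2_min, p_max, n_min))
  out <- do.call(rbind, lapply(maps, function(m) {
    data.frame(country_id = m$country_id, C_hat = m$C_hat, B_hat = m$B_hat,
               r2 = m$r2, p = m$p, n_obs = m$n_obs,
               included = m$country_id %in% sel)
  }))
  rownames(out) <- NULL
  out[order(out$country_id), ]
}

#' The France per-smoker consumption worked example
#'
#' Reproduces the arithmetic that motivates excluding an inconsistent survey
#' point: between two survey years, reported prevalence falls while per-capita
#' consumption rises, implying an implausible jump in consumption per smoker.
#' Per-smoker daily consumption is c(t) / x(t) (population cancels); the
#' percent changes at display precision are computed from the per-smoker
#' values rounded to one decimal, as conventionally reported.
#'
#' @param x1,x2 Survey prevalence fractions in the two years.
#' @param c1,c2 Per-capita consumption (g/person/day) in the two years.
#' @return List with per-smoker consumption (raw and at display precision)
#'   and the three percent changes.
#' @examples
#' france_worked_example()  # the 1960 vs 1965 inconsistency
#' @export
france_worked_example <- function(x1 = 0.32, x2 = 0.25, c1 = 3.6, c2 = 4.1) {
  stopifnot(x1 > 0, x2 > 0, c1 >= 0, c2 >= 0)
  # conventional half-up rounding for display values (base round() rounds
  # half to even: 11.25 would print as 11.2, not the conventional 11.3)
  half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  per1 <- c1 / x1
  per2 <- c2 / x2
  per1_disp <- half_up(per1, 1)
  per2_disp <- half_up(per2, 1)
  list(per_smoker_1 = per1, per_smoker_2 = per2,
       per_smoker_1_display = per1_disp, per_smoker_2_display = per2_disp,
       per_smoker_increase_pct = half_up(100 * (per2_disp - per1_disp) / per1_disp, 1),
       prevalence_decrease_pct = half_up(100 * (x1 - x2) / x1, 1),
       consumption_increase_pct = half_up(100 * (c2 - c1) / c1, 1))
}
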