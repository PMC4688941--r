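# Trend statistics and cross-country correlations.

#' Peak year of cigarette consumption
#'
#' The earliest year at which the recorded consumption attains its maximum.
#' Raw data, no smoothing: the choice of a smoothing algorithm would be
#' arbitrary and the result is robust without it. A model-trajectory-based
#' alternative is available through [predict.smoking_fit()] for sensitivity
#' checks but is never the default.
#'
#' @param series A [country_series()] or a data frame with columns `year`,
#'   `value`.
#' @return Integer year (earliest argmax).
#' @export
peak_year <- function(series) {
  df <- if (inherits(series, "country_series")) series$consumption else series
  stopifnot(is.data.frame(df), all(c("year", "value") %in% names(df)))
  if (nrow(df) == 0L) stop("cannot take the peak year of an empty series")
  df <- df[order(df$year), ]
  df$year[which.max(df$value)]
}

#' Average slope of estimated prevalence up to the peak year
#'
#' s_x = (x_hat(t_max) - x_hat(t0)) / (t_max - t0), with t0 = 1920 the first
#' year for which prevalence estimates exist in the seven-country subset.
#' Both endpoint years must be present exactly; no interpolation.
#'
#' @param xhat Data frame with columns `year`, `x_hat`.
#' @param t_max Peak year (see [peak_year()]).
#' @param t0 Reference year (default 1920).
#' @return s_x in fraction/year.
#' @export
average_slope <- function(xhat, t_max, t0 = 1920) {
  stopifnot(is.data.frame(xhat), all(c("year", "x_hat") %in% names(xhat)))
  if (t_max == t0) stop("t_max equals t0: average slope undefined")
  x_t0 <- xhat$x_hat[xhat$year == t0]
  x_tm <- xhat$x_hat[xhat$year == t_max]
  if (length(x_t0) != 1L) stop(sprintf("no prevalence estimate at t0 = %d", t0))
  if (length(x_tm) != 1L) stop(sprintf("no prevalence estimate at t_max = %d", t_max))
  (x_tm - x_t0) / (t_max - t0)
}

#' Pearson correlation with OLS line
#'
#' Pearson correlation coefficient with its two-sided p-value from the
#' t-statistic on n - 2 degrees of freedom, plus the slope and intercept of
#' the y-on-x least-squares line.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), no missing values.
#' @return An object of class `correlation_result`: `rho`, `p`, `slope`,
#'   `intercept`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  structure(list(rho = unname(ct$estimate), p = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> rho = %.3f, p = %.3g, slope = %.3g, intercept = %.3g, n = %d\n",
              x$rho, x$p, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Tidy table of trend correlations
#'
#' Computes the pairwise correlations linking the fitted conformity
#' parameter `a`, the average slope `s_x`, the peak year `t_max`, and the
#' individualism index IDV across countries.
#'
#' @param stats_df Data frame with one row per country, containing any of
#'   the columns `a`, `s_x`, `t_max`, `idv`.
#' @param pairs List of 2-element character vectors `c(x, y)`; defaults to
#'   the six analysis pairs (regressions of `a`, `s_x`, `t_max` on IDV and
#'   of `s_x`, `t_max` on `a`).
#' @return Data frame with columns `x`, `y`, `n`, `rho`, `p`, `slope`,
#'   `intercept` (rows with fewer than 3 complete pairs are dropped with a
#'   warning).
#' @export
trend_correlations <- function(stats_df,
                               pairs = list(c("idv", "a"), c("idv", "s_x"),
                                            c("idv", "t_max"), c("a", "s_x"),
                                            c("a", "t_max"))) {
  out <- lapply(pairs, function(pr) {
    if (!all(pr %in% names(stats_df))) return(NULL)
    d <- stats_df[stats::complete.cases(stats_df[, pr]), pr]
    if (nrow(d) < 3L) {
      warning(sprintf("fewer than 3 complete pairs for (%s, %s)", pr[1], pr[2]))
      return(NULL)
    }
    r <- pearson_correlation(d[[pr[1]]], d[[pr[2]]])
    data.frame(x = pr[1], y = pr[2], n = r$n, rho = r$rho, p = r$p,
               slope = r$slope, intercept = r$intercept)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Counterfactual cumulative cigarette consumption under shifted IDV
#'
#' Re-simulates one country's prevalence trajectory with its conformity
#' parameter shifted as a lower individualism index implies, converts both
#' the baseline and counterfactual prevalence to per-capita consumption
#' through the inverse affine map c = (x - B_hat) / C_hat, weights by the
#' (linearly interpolated) population and 365 days, and reports the percent
#' decrease in cumulative cigarettes over the window. The grams-to-
#' cigarettes conversion cancels in the ratio. The IDV reduction is
#' multiplicative (a percentage of the index value, not index points) and
#' maps to a parameter shift through the fitted a-on-IDV regression slope.
#'
#' @param fit A [fit_smoking_model()] result.
#' @param country Country label in the fit.
#' @param map The country's [fit_linear_map()] result (`C_hat > 0`).
#' @param a_idv_slope Fitted OLS slope of `a` on IDV (negative under the
#'   model's interpretation).
#' @param idv The country's IDV value.
#' @param delta_idv_pct Percent reduction applied to IDV (e.g. 2).
#' @param population Data frame with columns `year`, `persons`, covering the
#'   window.
#' @param window Length-2 integer vector of years, default `c(1920, 2010)`.
#' @return List with `percent_decrease`, `a_baseline`, `a_counterfactual`,
#'   and the two cumulative totals (arbitrary common units).
#' @export
counterfactual_consumption <- function(fit, country, map, a_idv_slope, idv,
                                       delta_idv_pct, population,
                                       window = c(1920, 2010)) {
  stopifnot(inherits(fit, "smoking_fit"), country %in% names(fit$data))
  if (map$C_hat <= 0) stop("inverse map requires a positive slope C_hat")
  years <- seq(window[1], window[2])
  if (min(population$year) > window[1] || max(population$year) < window[2]) {
    stop("population series does not cover the counterfactual window")
  }
  pop <- stats::approx(population$year, population$persons, xout = years)$y
  if (anyNA(pop)) stop("population series has gaps over the window")

  loc <- fit$locals_list[[country]]
  obs <- fit$data[[country]]
  a0 <- loc[["a"]]
  a1 <- min(max(a0 + a_idv_slope * (idv * (1 - delta_idv_pct / 100) - idv), 0), 2)

  if (obs$year[1] > window[1]) {
    stop("window starts before the country's first observation year")
  }
  traj_for <- function(a) {
    l <- loc; l[["a"]] <- a
    spec <- make_utility(fit$form, l, fit$universals,
                         fit$t_star_list[[country]])
    simulate_prevalence(a = a, b = fit$universals[["b"]], x0 = l[["x0"]],
                        t0 = obs$year[1], spec = spec,
                        years = years, curve = fit$curve)$x
  }
  cum_for <- function(x) {
    c_t <- (x - map$B_hat) / map$C_hat
    sum(pmax(c_t, 0) * pop * 365)
  }
  base <- cum_for(traj_for(a0))
  cf <- cum_for(traj_for(a1))
  list(percent_decrease = 100 * (1 - cf / base),
       a_baseline = a0, a_counterfactual = a1,
       cumulative_baseline = base, cumulative_counterfactual = cf)
}
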