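# Methods for fitted smoking-prevalence models.

#' @export
print.smoking_fit <- function(x, ...) {
  cat(sprintf("Smoking-prevalence social-dynamics fit (%s utility)\n", x$form))
  cat(sprintf("  countries: %d   outer iterations: %d%s\n",
              nrow(x$locals), x$iterations,
              if (x$converged) "" else "   (iteration cap reached)"))
  cat("  universal parameters: ",
      paste(names(x$universals), signif(x$universals, 4), sep = " = ",
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  total squared-L2 error E_2 = %.4g\n", x$E2))
  invisible(x)
}

#' Summarise a fitted smoking-prevalence model
#'
#' @param object A [fit_smoking_model()] result.
#' @param ... Unused.
#' @return An object of class `summary.smoking_fit`: the per-country local
#'   parameter and error table, the universal parameters, and convergence
#'   diagnostics.
#' @export
summary.smoking_fit <- function(object, ...) {
  structure(list(form = object$form,
                 locals = object$locals,
                 universals = object$universals,
                 E2 = object$E2,
                 iterations = object$iterations,
                 converged = object$converged,
                 country_converged = object$country_converged,
                 E2_history = object$E2_history),
            class = "summary.smoking_fit")
}

#' @export
print.summary.smoking_fit <- function(x, ...) {
  cat(sprintf("Smoking-prevalence social-dynamics fit (%s utility)\n\n", x$form))
  cat("Universal parameters:\n")
  print(signif(x$universals, 4))
  cat("\nLocal parameters and per-country errors:\n")
  tab <- x$locals
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("\nTotal error E_2 = %.4g after %d outer iteration(s)%s\n",
              x$E2, x$iterations,
              if (x$converged) " (converged)" else " (cap reached)"))
  if (!all(x$country_converged)) {
    cat("Local fits flagged as not fully converged:",
        paste(names(which(!x$country_converged)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract fitted parameters
#'
#' @param object A [fit_smoking_model()] result.
#' @param which `"all"` (default) for universals plus per-country locals as
#'   a named vector, `"universal"` or `"local"` for the parts.
#' @param ... Unused.
#' @export
coef.smoking_fit <- function(object, which = c("all", "universal", "local"),
                             ...) {
  which <- match.arg(which)
  loc <- unlist(lapply(names(object$locals_list), function(k) {
    v <- object$locals_list[[k]]
    stats::setNames(v, paste(names(v), k, sep = "."))
  }))
  switch(which,
    universal = object$universals,
    local = loc,
    all = c(object$universals, loc))
}

#' Model-predicted prevalence trajectories
#'
#' @param object A [fit_smoking_model()] result.
#' @param years Optional vector of output years; defaults to each country's
#'   observation years. A single shared vector applies to all countries
#'   (truncated below each country's initial year).
#' @param countries Optional subset of country labels.
#' @param ... Unused.
#' @return Data frame with columns `country`, `year`, `x`.
#' @export
predict.smoking_fit <- function(object, years = NULL, countries = NULL, ...) {
  ks <- countries %||% names(object$data)
  stopifnot(all(ks %in% names(object$data)))
  out <- do.call(rbind, lapply(ks, function(k) {
    obs <- object$data[[k]]
    yrs <- if (is.null(years)) obs$year else sort(years[years >= obs$year[1]])
    loc <- object$locals_list[[k]]
    spec <- make_utility(object$form, loc, object$universals,
                         object$t_star_list[[k]])
    traj <- simulate_prevalence(a = loc[["a"]], b = object$universals[["b"]],
                                x0 = loc[["x0"]], t0 = obs$year[1],
                                spec = spec, years = yrs,
                                curve = object$curve)
    data.frame(country = k, year = traj$year, x = traj$x)
  }))
  rownames(out) <- NULL
  out
}

#' @export
fitted.smoking_fit <- function(object, ...) predict(object)

#' Calibration residuals (model minus estimated prevalence)
#'
#' @param object A [fit_smoking_model()] result.
#' @param ... Unused.
#' @return Data frame with columns `country`, `year`, `residual`.
#' @export
residuals.smoking_fit <- function(object, ...) {
  fit <- predict(object)
  obs <- do.call(rbind, lapply(names(object$data), function(k) {
    data.frame(country = k, year = object$data[[k]]$year,
               x_hat = object$data[[k]]$x_hat)
  }))
  m <- merge(fit, obs, by = c("country", "year"))
  out <- data.frame(country = m$country, year = m$year,
                    residual = m$x - m$x_hat)
  out[order(out$country, out$year), ]
}

#' Plot estimated prevalence and fitted model curves
#'
#' One panel per country: estimated prevalence points overlaid with the
#' fitted model trajectory on a dense annual grid.
#'
#' @param x A [fit_smoking_model()] result.
#' @param countries Optional subset of country labels.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.smoking_fit <- function(x, countries = NULL, ...) {
  ks <- countries %||% names(x$data)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(ks)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in ks) {
    obs <- x$data[[k]]
    grid <- seq(obs$year[1], max(obs$year))
    pred <- predict(x, years = grid, countries = k)
    graphics::plot(obs$year, obs$x_hat, xlab = "year",
                   ylab = "smoking prevalence", main = k,
                   ylim = range(c(obs$x_hat, pred$x, 0)), ...)
    graphics::lines(pred$year, pred$x, col = "steelblue", lwd = 2)
  }
  invisible(x)
}
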