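# Seeded synthetic study inputs.
#
# The generator inverts the analysis chain: per-country prevalence
# trajectories come from the dynamical model itself, consumption is obtained
# through the inverse affine map plus Gaussian noise, sparse surveys add
# Gaussian noise to the true prevalence, the article curve is a saturating
# logistic rate with optional Poisson jitter, and the individualism index is
# linear in the true conformity parameter (negative slope) plus noise. In
# the noise-free limit the full pipeline is a statistical identity.

#' Generate a synthetic article-count series
#'
#' Yearly publication counts follow a logistic (accelerating-then-
#' saturating) rate curve, optionally jittered with Poisson noise; the
#' cumulative column is the running sum, so the records always satisfy the
#' article-CSV consistency rules.
#'
#' @param start_year,end_year Inclusive year range.
#' @param peak_rate Asymptotic articles/year of the logistic rate.
#' @param midpoint Year at which the rate reaches half its asymptote.
#' @param steepness Logistic growth rate (1/years); 0 gives a constant rate
#'   of `peak_rate / 2`.
#' @param jitter Add Poisson noise to the yearly counts?
#' @param seed Integer seed (required when `jitter = TRUE`).
#' @return Data frame with columns `year`, `published`, `cumulative`.
#' @export
synth_articles <- function(start_year = 1900, end_year = 2012,
                           peak_rate = 2000, midpoint = 1990,
                           steepness = 0.12, jitter = TRUE, seed = NULL) {
  stopifnot(start_year < end_year, peak_rate > 0, steepness >= 0)
  years <- seq(start_year, end_year)
  rate <- peak_rate / (1 + exp(-steepness * (years - midpoint)))
  published <- if (jitter) {
    if (is.null(seed)) stop("a seed is required for jittered article counts")
    set.seed(seed)
    stats::rpois(length(years), rate)
  } else {
    round(rate)
  }
  data.frame(year = years, published = as.integer(published),
             cumulative = as.integer(cumsum(published)))
}

#' Specify one synthetic country
#'
#' @param a,x0,u0,u_inf True local model parameters (within the calibration
#'   bounds).
#' @param C,B True affine consumption-to-prevalence map (`C > 0`).
#' @param sigma_x Survey noise s.d. (prevalence fraction).
#' @param sigma_c Consumption noise s.d. (g/person/day).
#' @param survey_years Years at which prevalence surveys are observed.
#' @param idv Individualism-index value attached to the country.
#' @return An object of class `synth_country_spec`.
#' @export
synth_country_spec <- function(a, x0, u0, u_inf, C, B,
                               sigma_x = 0.01, sigma_c = 0.1,
                               survey_years = seq(1960, 2012, by = 2),
                               idv = NA_real_) {
  stopifnot(a >= 0, a <= 2, x0 >= 0, x0 <= 1, u0 >= 0, u0 <= 1,
            u_inf >= 0, u_inf <= 1, C > 0, sigma_x >= 0, sigma_c >= 0)
  structure(list(a = a, x0 = x0, u0 = u0, u_inf = u_inf, C = C, B = B,
                 sigma_x = sigma_x, sigma_c = sigma_c,
                 survey_years = survey_years, idv = idv),
            class = "synth_country_spec")
}

#' Generate one synthetic country's tobacco-use series
#'
#' Simulates the true prevalence x(t) from the model, observes consumption
#' c(t) = (x(t) - B)/C plus Gaussian noise every year (truncated at 0 to
#' respect the data contract), and observes prevalence surveys
#' x(t) + Gaussian noise (truncated to `[0, 1]`) at the survey years only.
#'
#' @param country_id Country identifier.
#' @param spec A [synth_country_spec()].
#' @param b,delta Universal parameters shared across the panel.
#' @param curve A [knowledge_curve()].
#' @param years Consumption observation years (default 1920-2012, annual).
#' @param seed Integer seed.
#' @return A [country_series()]; the true trajectory is attached as
#'   attribute `truth`.
#' @export
synth_country <- function(country_id, spec, b, delta, curve,
                          years = 1920:2012, seed = 1) {
  stopifnot(inherits(spec, "synth_country_spec"))
  uspec <- utility_spec("discounted", u0 = spec$u0, u_inf = spec$u_inf,
                        delta = delta)
  traj <- simulate_prevalence(a = spec$a, b = b, x0 = spec$x0, t0 = years[1],
                              spec = uspec, years = years, curve = curve)
  set.seed(seed)
  c_true <- (traj$x - spec$B) / spec$C
  c_obs <- pmax(c_true + stats::rnorm(length(c_true), 0, spec$sigma_c), 0)
  sy <- spec$survey_years[spec$survey_years %in% years]
  x_true <- traj$x[match(sy, traj$year)]
  x_obs <- pmin(pmax(x_true + stats::rnorm(length(sy), 0, spec$sigma_x), 0), 1)
  out <- country_series(country_id,
                        prevalence = data.frame(year = sy, value = x_obs),
                        consumption = data.frame(year = years, value = c_obs))
  attr(out, "truth") <- traj
  out
}

# Unstable interior equilibrium of the rate law for conformity a > 1 and
# utility u: below it prevalence collapses toward 0, above it the epidemic
# can take off. Rise-and-fall trajectories require x0 above this threshold
# at the no-knowledge utility u0 (the fitted countries all sit just above
# it). For a <= 1 any positive x0 grows when u > 1/2.
adoption_threshold <- function(a, u) {
  if (a <= 1 || u <= 0.5) return(0)
  r <- ((1 - u) / u)^(1 / (a - 1))
  r / (1 + r)
}

# Survey schedule mimicking the sparse survey record: visits every 2-3 years
# from 1960 on.
survey_schedule <- function(from = 1960, to = 2012) {
  steps <- rep(c(2L, 3L), length.out = 30)[sample.int(30)]
  yrs <- cumsum(c(from, steps))
  yrs[yrs <= to]
}

#' Generate a complete synthetic study panel
#'
#' Draws per-country true parameters (conformity `a` uniform on
#' `[0.9, 1.2]`, the fitted range; initial prevalence, limiting utilities
#' and affine maps within the observed ranges), rejection-sampling each
#' draw until the model trajectory shows the rise-and-fall shape of the
#' study data, shares the universal parameters across countries, builds a
#' synthetic article curve, and attaches an individualism index
#' IDV = 120 - 90 a + N(0, 5) (clamped to `[0, 100]`), so the true a-IDV
#' slope is negative. Optionally writes the three input CSVs in the
#' standard dialects.
#'
#' @param n_countries Number of countries (>= 1).
#' @param seed Master seed; the same seed reproduces the panel bitwise.
#' @param b,delta Universal parameters (defaults: the fitted values 1.049
#'   and 0.9981).
#' @param sigma_x,sigma_c Observation noise s.d.s (defaults 0.01 and 0.1;
#'   set both to 0 for the noise-free limit).
#' @param years Consumption years (default 1920-2012).
#' @param dir Optional directory; if given, writes `tobacco.csv`,
#'   `articles.csv`, `registry.csv` there.
#' @return An object of class `synth_panel`: fields `panel` (a
#'   `tobacco_panel`), `articles`, `registry`, `truth` (per-country true
#'   parameters), `b`, `delta`, `seed`, and `paths` when written.
#' @export
synth_panel <- function(n_countries = 7, seed = 1, b = 1.049, delta = 0.9981,
                        sigma_x = 0.01, sigma_c = 0.1, years = 1920:2012,
                        dir = NULL) {
  stopifnot(n_countries >= 1)
  set.seed(seed)
  arts <- synth_articles(jitter = TRUE, seed = seed + 1000L)
  curve <- knowledge_curve(arts)

  # Rejection-sample each country's true parameters until the model
  # trajectory has the rise-and-fall shape of the study data: an interior
  # peak (neither immediate collapse nor saturation at the ceiling) followed
  # by a clear decline. For a > 1 the no-knowledge utility u0 is solved from
  # the adoption threshold so it sits safely below x0 (the fitted countries
  # all pair large a with large u0 in exactly this way).
  draw_one <- function() {
    a <- stats::runif(1, 0.9, 1.2)
    x0 <- stats::runif(1, 0.05, 0.2)
    u0_flat <- stats::runif(1, 0.51, 0.555)
    thr_frac <- stats::runif(1, 0.55, 0.85)
    u_inf <- stats::runif(1, 0.475, 0.51)
    u0 <- if (a <= 1) u0_flat else {
      xthr <- x0 * thr_frac
      min(max(1 / (1 + (xthr / (1 - xthr))^(a - 1)), 0.51), 0.6)
    }
    list(a = a, x0 = x0, u0 = max(u0, u_inf + 0.02), u_inf = u_inf,
         C = stats::runif(1, 0.04, 0.07), B = stats::runif(1, 0, 0.03))
  }
  # interior peak in the era the data shows, bounded height, a real decline
  # afterwards, and prevalence staying above the zero-consumption intercept
  # B so the implied consumption is positive throughout
  rise_and_fall <- function(p) {
    spec <- utility_spec("discounted", u0 = p$u0, u_inf = p$u_inf,
                         delta = delta)
    tr <- simulate_prevalence(p$a, b, p$x0, years[1], spec, years, curve)
    pk <- which.max(tr$x)
    xmax <- tr$x[pk]
    tr$year[pk] > 1945 && tr$year[pk] < 2000 &&
      xmax >= 0.15 && xmax <= 0.65 &&
      tr$x[nrow(tr)] <= 0.9 * xmax &&
      min(tr$x) >= p$B + 0.01
  }
  specs <- vector("list", n_countries)
  for (i in seq_len(n_countries)) {
    p <- NULL
    for (try in 1:100) {
      p <- draw_one()
      if (rise_and_fall(p)) break
      if (try == 100) stop("could not draw a rise-and-fall country in 100 tries")
    }
    idv_i <- min(max(120 - 90 * p$a + stats::rnorm(1, 0, 5), 0), 100)
    specs[[i]] <- synth_country_spec(
      p$a, p$x0, p$u0, p$u_inf, C = p$C, B = p$B,
      sigma_x = sigma_x, sigma_c = sigma_c,
      survey_years = survey_schedule(), idv = idv_i)
  }
  a <- vapply(specs, `[[`, numeric(1), "a")
  x0 <- vapply(specs, `[[`, numeric(1), "x0")
  u0 <- vapply(specs, `[[`, numeric(1), "u0")
  u_inf <- vapply(specs, `[[`, numeric(1), "u_inf")
  C <- vapply(specs, `[[`, numeric(1), "C")
  B <- vapply(specs, `[[`, numeric(1), "B")
  idv <- vapply(specs, `[[`, numeric(1), "idv")
  series <- lapply(seq_len(n_countries), function(i) {
    synth_country(i, specs[[i]], b, delta, curve, years,
                  seed = seed + 2000L + i)
  })
  names(series) <- as.character(seq_len(n_countries))
  panel <- structure(series, class = "tobacco_panel")
  registry <- data.frame(country_id = seq_len(n_countries),
                         name = sprintf("Synthia-%02d", seq_len(n_countries)),
                         idv = round(idv, 1))
  truth <- data.frame(country_id = seq_len(n_countries), a = a, x0 = x0,
                      u0 = u0, u_inf = u_inf, C = C, B = B, idv = idv)

  out <- structure(list(panel = panel, articles = arts, registry = registry,
                        truth = truth, b = b, delta = delta, seed = seed,
                        specs = specs),
                   class = "synth_panel")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(tobacco = file.path(dir, "tobacco.csv"),
                  articles = file.path(dir, "articles.csv"),
                  registry = file.path(dir, "registry.csv"))
    write_tobacco_csv(panel, paths$tobacco)
    utils::write.csv(arts, paths$articles, row.names = FALSE, quote = FALSE)
    utils::write.csv(registry, paths$registry, row.names = FALSE, quote = FALSE)
    out$paths <- paths
  }
  out
}

#' @export
print.synth_panel <- function(x, ...) {
  cat(sprintf("<synth_panel> %d countries, seed %d, b = %g, delta = %g\n",
              nrow(x$truth), x$seed, x$b, x$delta))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Runs the full pipeline (affine map fits, prevalence estimation,
#' alternating calibration, trend statistics) on freshly generated synthetic
#' panels and reports the recovery error of every parameter.
#'
#' @param replicates Number of replicate panels (>= 1).
#' @param n_countries Countries per panel.
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param sigma_x,sigma_c Observation noise levels.
#' @param config A [fit_config()] for the calibration stage.
#' @param years Consumption years per country.
#' @return A list with `per_country` (one row per replicate x country:
#'   true and recovered a, x0, u0, u_inf, C, B, plus s_x and t_max recovered
#'   vs true), `universals` (per replicate: recovered b, delta, E2), and
#'   `summary` (bias and RMSE per parameter).
#' @export
recovery_experiment <- function(replicates = 1, n_countries = 3, seed = 1,
                                sigma_x = 0.01, sigma_c = 0.1,
                                config = fit_config(), years = 1920:2012) {
  stopifnot(replicates >= 1)
  rows <- list(); unis <- list()
  for (r in seq_len(replicates)) {
    sp <- synth_panel(n_countries, seed = seed + r, sigma_x = sigma_x,
                      sigma_c = sigma_c, years = years)
    curve <- knowledge_curve(sp$articles)
    maps <- lapply(sp$panel, fit_linear_map)
    xhat <- lapply(names(sp$panel), function(k) {
      estimate_prevalence(sp$panel[[k]], maps[[k]])
    })
    names(xhat) <- names(sp$panel)
    fit <- fit_smoking_model(xhat, curve, form = "discounted", config = config)

    rows[[r]] <- do.call(rbind, lapply(seq_along(sp$panel), function(i) {
      k <- names(sp$panel)[i]
      loc <- fit$locals_list[[k]]
      truth <- sp$truth[i, ]
      tmax_obs <- peak_year(sp$panel[[k]])
      tmax_true <- peak_year(data.frame(year = attr(sp$panel[[k]], "truth")$year,
                                        value = attr(sp$panel[[k]], "truth")$x))
      sx <- tryCatch(average_slope(xhat[[k]], tmax_obs), error = function(e) NA)
      data.frame(replicate = r, country_id = truth$country_id,
                 a_true = truth$a, a_hat = loc[["a"]],
                 x0_true = truth$x0, x0_hat = loc[["x0"]],
                 u0_true = truth$u0, u0_hat = loc[["u0"]],
                 u_inf_true = truth$u_inf, u_inf_hat = loc[["u_inf"]],
                 C_true = truth$C, C_hat = maps[[k]]$C_hat,
                 B_true = truth$B, B_hat = maps[[k]]$B_hat,
                 idv = truth$idv, s_x = sx,
                 t_max = tmax_obs, t_max_true = tmax_true)
    }))
    unis[[r]] <- data.frame(replicate = r, b = fit$universals[["b"]],
                            delta = fit$universals[["delta"]], E2 = fit$E2,
                            iterations = fit$iterations,
                            converged = fit$converged)
  }
  per_country <- do.call(rbind, rows)
  universals <- do.call(rbind, unis)
  pars <- c("a", "x0", "u0", "u_inf", "C", "B")
  summary <- do.call(rbind, lapply(pars, function(p) {
    err <- per_country[[paste0(p, "_hat")]] - per_country[[paste0(p, "_true")]]
    data.frame(parameter = p, bias = mean(err), rmse = sqrt(mean(err^2)))
  }))
  list(per_country = per_country, universals = universals, summary = summary)
}
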