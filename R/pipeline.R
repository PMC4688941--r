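# End-to-end study pipeline: ingest -> estimate -> calibrate -> statistics.

#' Configure a study run
#'
#' @param tobacco,articles,registry Paths to the three input CSVs.
#' @param population Optional path to a population CSV (for the
#'   counterfactual stage; not run by [run_study()] itself).
#' @param r2_min,p_max,n_min Inclusion-filter thresholds.
#' @param exclude Data frame with columns `country_id`, `year`: survey
#'   points removed before the affine regression (analyst-driven outlier
#'   exclusions; [grubbs_screen()] is the audit tool).
#' @param form Utility form for the calibration.
#' @param fit A [fit_config()].
#' @param t0 Reference year for the average slope.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters when the inputs were generated).
#' @return An object of class `study_config`.
#' @export
study_config <- function(tobacco, articles, registry, population = NULL,
                         r2_min = 0.7, p_max = 0.001, n_min = 15,
                         exclude = data.frame(country_id = integer(),
                                              year = integer()),
                         form = "discounted", fit = fit_config(), t0 = 1920,
                         seed = NA_integer_) {
  for (p in c(tobacco, articles, registry, population)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
  }
  structure(list(tobacco = tobacco, articles = articles, registry = registry,
                 population = population, r2_min = r2_min, p_max = p_max,
                 n_min = n_min, exclude = exclude, form = form, fit = fit,
                 t0 = t0, seed = seed),
            class = "study_config")
}

# Stable hash of the configuration for the run log.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full study pipeline
#'
#' Reads the inputs, fits the per-country affine maps (after the configured
#' outlier exclusions), applies the inclusion filter, estimates historical
#' prevalence, calibrates the dynamical model by alternating least squares,
#' computes trend statistics and correlations, and writes every intermediate
#' artifact to `out_dir` (`maps.csv`, `universals.csv`, `locals.csv`,
#' `stats.csv`, `correlations.csv`, `trajectories.csv`, `run_log.txt`).
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the fitted objects and tables; also
#'   written to disk.
#' @export
run_study <- function(config, out_dir) {
  stopifnot(inherits(config, "study_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(sprintf("smokedyn %s | %s | config %s | seed %s",
                         as.character(utils::packageVersion("smokedyn")),
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                         config_hash(config), config$seed))
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  panel <- read_tobacco_csv(config$tobacco)
  articles <- read_article_csv(config$articles)
  registry <- read_country_table(config$registry)
  curve <- knowledge_curve(articles)
  note("read %d countries, %d article years", length(panel), nrow(articles))

  maps <- lapply(panel, function(s) {
    excl <- config$exclude$year[config$exclude$country_id == s$country_id]
    if (length(excl)) note("country %d: excluding survey years %s",
                           s$country_id, paste(excl, collapse = ", "))
    tryCatch(fit_linear_map(s, exclude_years = excl),
             error = function(e) { note("country %d: map not fitted (%s)",
                                        s$country_id, conditionMessage(e)); NULL })
  })
  maps <- Filter(Negate(is.null), maps)
  mtab <- map_table(maps, config$r2_min, config$p_max, config$n_min)
  utils::write.csv(mtab, file.path(out_dir, "maps.csv"), row.names = FALSE)

  sel <- suppressWarnings(
    select_countries(maps, config$r2_min, config$p_max, config$n_min))
  if (length(sel) == 0L) {
    note("no country passes the inclusion filter; stopping after the map stage")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    return(invisible(list(maps = maps, map_table = mtab, selected = sel)))
  }
  note("inclusion filter keeps %d countries: %s", length(sel),
       paste(sel, collapse = ", "))

  name_of <- function(id) {
    nm <- registry$name[registry$country_id == id]
    if (length(nm) == 1L && nzchar(nm)) nm else as.character(id)
  }
  xhat <- lapply(sel, function(id) {
    estimate_prevalence(panel[[as.character(id)]], maps[[as.character(id)]])
  })
  names(xhat) <- vapply(sel, name_of, "")

  fit <- fit_smoking_model(xhat, curve, form = config$form, config = config$fit)
  note("calibration: E_2 = %.6g after %d outer iterations (%s)", fit$E2,
       fit$iterations, if (fit$converged) "converged" else "cap reached")
  utils::write.csv(data.frame(t(fit$universals), E2 = fit$E2,
                              iterations = fit$iterations),
                   file.path(out_dir, "universals.csv"), row.names = FALSE)
  utils::write.csv(fit$locals, file.path(out_dir, "locals.csv"),
                   row.names = FALSE)
  utils::write.csv(predict(fit), file.path(out_dir, "trajectories.csv"),
                   row.names = FALSE)

  stats_df <- do.call(rbind, lapply(seq_along(sel), function(i) {
    id <- sel[i]; k <- names(xhat)[i]
    tm <- peak_year(panel[[as.character(id)]])
    sx <- tryCatch(average_slope(xhat[[k]], tm, t0 = config$t0),
                   error = function(e) { note("country %d: s_x unavailable (%s)",
                                              id, conditionMessage(e)); NA })
    data.frame(country_id = id, country = k,
               a = fit$locals_list[[k]][["a"]], s_x = sx, t_max = tm,
               idv = registry$idv[match(id, registry$country_id)])
  }))
  utils::write.csv(stats_df, file.path(out_dir, "stats.csv"),
                   row.names = FALSE)
  cors <- trend_correlations(stats_df)
  if (!is.null(cors)) {
    utils::write.csv(cors, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(maps = maps, map_table = mtab, selected = sel, xhat = xhat,
                 fit = fit, stats = stats_df, correlations = cors))
}
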