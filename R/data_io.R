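#' @keywords internal
#' @useDynLib smokedyn
"_PACKAGE"

# Shared validators ---------------------------------------------------------

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

#' Read a raw CSV with an optional header row
#'
#' The input dialects carry no mandated header; a header is detected by a
#' non-numeric first field on the first line.
#'
#' @noRd
read_maybe_header <- function(path, ncol, col_names) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(trimws(first))) {
    return(list(df = NULL, offset = 0L))
  }
  f1 <- strsplit(first, ",", fixed = TRUE)[[1]][1]
  has_header <- is.na(suppressWarnings(as.numeric(trimws(f1))))
  df <- utils::read.csv(path, header = has_header,
                        colClasses = "character",
                        strip.white = TRUE, blank.lines.skip = TRUE)
  if (nrow(df) == 0L) return(list(df = NULL, offset = as.integer(has_header)))
  if (ncol(df) != ncol) {
    stop(sprintf("%s: expected %d columns, found %d", path, ncol, ncol(df)),
         call. = FALSE)
  }
  names(df) <- col_names
  list(df = df, offset = as.integer(has_header))
}

num_field <- function(x, path, lines, what, integer = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | !is.finite(v))
  if (length(bad)) {
    stop_parse(path, lines[bad[1]], sprintf("malformed %s field '%s'",
                                            what, x[bad[1]]))
  }
  if (integer) {
    nb <- which(v != round(v))
    if (length(nb)) {
      stop_parse(path, lines[nb[1]],
                 sprintf("%s must be an integer, got '%s'", what, x[nb[1]]))
    }
    v <- as.integer(round(v))
  }
  v
}

# Country series and panels --------------------------------------------------

#' Construct a single-country tobacco-use series
#'
#' Holds survey smoking prevalence (fraction of the population) and
#' manufactured cigarette consumption (grams per person per day) for one
#' country, each as a year-sorted table.
#'
#' @param country_id Positive integer country identifier.
#' @param prevalence Data frame with columns `year`, `value` (fractions in
#'   `[0, 1]`).
#' @param consumption Data frame with columns `year`, `value` (grams per
#'   person per day, nonnegative).
#' @param name Optional country name.
#' @return An object of class `country_series`.
#' @export
country_series <- function(country_id, prevalence = NULL, consumption = NULL,
                           name = NULL) {
  empty <- data.frame(year = integer(), value = numeric())
  prevalence <- if (is.null(prevalence)) empty else prevalence
  consumption <- if (is.null(consumption)) empty else consumption
  for (nm in c("prevalence", "consumption")) {
    df <- get(nm)
    stopifnot(is.data.frame(df), all(c("year", "value") %in% names(df)))
    if (nrow(df) && any(df$year != round(df$year))) {
      stop("years must be whole calendar years", call. = FALSE)
    }
    df$year <- as.integer(df$year)
    df <- df[order(df$year), c("year", "value")]
    rownames(df) <- NULL
    if (anyDuplicated(df$year)) {
      stop(sprintf("duplicate (country %s, year, %s) measurement",
                   country_id, nm), call. = FALSE)
    }
    assign(nm, df)
  }
  if (any(prevalence$value < 0 | prevalence$value > 1)) {
    stop("prevalence values must be fractions in [0, 1]", call. = FALSE)
  }
  if (any(consumption$value < 0)) {
    stop("consumption values must be nonnegative", call. = FALSE)
  }
  structure(list(country_id = as.integer(country_id),
                 name = name %||% paste("country", country_id),
                 prevalence = prevalence, consumption = consumption),
            class = "country_series")
}

#' @export
print.country_series <- function(x, ...) {
  cat(sprintf("<country_series> %s (id %d): %d prevalence surveys, %d consumption years\n",
              x$name, x$country_id, nrow(x$prevalence), nrow(x$consumption)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tobacco-use CSV
#'
#' The file has four columns: country number, calendar year, measurement, and
#' a type flag (0 = smoking-prevalence fraction, 1 = cigarette consumption in
#' g/person/day). A header row is optional. Prevalence given in percent
#' (any value above 1) is rejected, never rescaled.
#'
#' @param path Path to the CSV file.
#' @return A named list of [country_series()] objects (class
#'   `tobacco_panel`), keyed by country id.
#' @export
read_tobacco_csv <- function(path) {
  stopifnot(file.exists(path))
  parsed <- read_maybe_header(path, 4L,
                              c("country_id", "year", "value", "flag"))
  if (is.null(parsed$df)) {
    warning(sprintf("%s: no tobacco records found", path))
    return(structure(list(), class = "tobacco_panel"))
  }
  df <- parsed$df
  lines <- seq_len(nrow(df)) + parsed$offset
  cid <- num_field(df$country_id, path, lines, "country number", integer = TRUE)
  year <- num_field(df$year, path, lines, "year", integer = TRUE)
  value <- num_field(df$value, path, lines, "measurement")
  flag <- num_field(df$flag, path, lines, "type flag", integer = TRUE)

  bad <- which(!flag %in% c(0L, 1L))
  if (length(bad)) {
    stop_parse(path, lines[bad[1]],
               sprintf("type flag must be 0 or 1, got %d", flag[bad[1]]))
  }
  bad <- which(cid < 1L)
  if (length(bad)) stop_parse(path, lines[bad[1]], "country number must be positive")
  bad <- which(year < 1850L | year > 2100L)
  if (length(bad)) {
    stop_parse(path, lines[bad[1]], sprintf("year %d outside [1850, 2100]", year[bad[1]]))
  }
  bad <- which(flag == 0L & (value < 0 | value > 1))
  if (length(bad)) {
    stop_parse(path, lines[bad[1]],
               sprintf("prevalence %g is not a fraction in [0, 1] (percent input is rejected, not rescaled)",
                       value[bad[1]]))
  }
  bad <- which(flag == 1L & value < 0)
  if (length(bad)) stop_parse(path, lines[bad[1]], "negative consumption")
  key <- paste(cid, year, flag)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("%s: duplicate (country, year, kind) measurement: %s", path, d),
         call. = FALSE)
  }

  panel <- lapply(sort(unique(cid)), function(id) {
    sel <- cid == id
    country_series(
      id,
      prevalence = data.frame(year = year[sel & flag == 0L],
                              value = value[sel & flag == 0L]),
      consumption = data.frame(year = year[sel & flag == 1L],
                               value = value[sel & flag == 1L]))
  })
  names(panel) <- vapply(panel, function(s) as.character(s$country_id), "")
  structure(panel, class = "tobacco_panel")
}

#' Read an article-count CSV
#'
#' Three columns: year, number of articles published that year, and the
#' cumulative number of articles published up to and including that year.
#' The cumulative column must be nondecreasing, and for consecutive years
#' must increase by exactly that year's published count.
#'
#' @param path Path to the CSV file.
#' @return A year-sorted data frame with columns `year`, `published`,
#'   `cumulative`.
#' @export
read_article_csv <- function(path) {
  stopifnot(file.exists(path))
  parsed <- read_maybe_header(path, 3L, c("year", "published", "cumulative"))
  if (is.null(parsed$df)) {
    warning(sprintf("%s: no article records found", path))
    return(data.frame(year = integer(), published = integer(),
                      cumulative = integer()))
  }
  df <- parsed$df
  lines <- seq_len(nrow(df)) + parsed$offset
  year <- num_field(df$year, path, lines, "year", integer = TRUE)
  published <- num_field(df$published, path, lines, "published count",
                         integer = TRUE)
  cumulative <- num_field(df$cumulative, path, lines, "cumulative count",
                          integer = TRUE)
  bad <- which(published < 0L | cumulative < 0L)
  if (length(bad)) stop_parse(path, lines[bad[1]], "negative article count")
  if (anyDuplicated(year)) {
    stop(sprintf("%s: duplicate year in article records", path), call. = FALSE)
  }
  ord <- order(year)
  out <- data.frame(year = year[ord], published = published[ord],
                    cumulative = cumulative[ord])
  if (nrow(out) > 1L) {
    dc <- diff(out$cumulative)
    if (any(dc < 0L)) {
      stop(sprintf("%s: cumulative article count decreases at year %d", path,
                   out$year[which(dc < 0L)[1] + 1L]), call. = FALSE)
    }
    consec <- which(diff(out$year) == 1L)
    mismatch <- consec[dc[consec] != out$published[consec + 1L]]
    if (length(mismatch)) {
      stop(sprintf("%s: cumulative count at year %d inconsistent with published count",
                   path, out$year[mismatch[1] + 1L]), call. = FALSE)
    }
  }
  out
}

#' Read the country registry
#'
#' Maps the opaque country number to a display name and (optionally) an
#' individualism-index (IDV) value on the 0-100 scale. Blank IDV fields are
#' stored as `NA`, never as 0.
#'
#' @param path Path to a CSV with columns `country_id`, `name`, `idv`.
#' @return A data frame with columns `country_id`, `name`, `idv`.
#' @export
read_country_table <- function(path) {
  stopifnot(file.exists(path))
  parsed <- read_maybe_header(path, 3L, c("country_id", "name", "idv"))
  if (is.null(parsed$df)) {
    return(data.frame(country_id = integer(), name = character(),
                      idv = numeric()))
  }
  df <- parsed$df
  lines <- seq_len(nrow(df)) + parsed$offset
  cid <- num_field(df$country_id, path, lines, "country id", integer = TRUE)
  if (anyDuplicated(cid)) {
    stop(sprintf("%s: duplicate country id %d", path, cid[duplicated(cid)][1]),
         call. = FALSE)
  }
  idv_raw <- trimws(df$idv)
  idv <- rep(NA_real_, length(idv_raw))
  has <- nzchar(idv_raw)
  if (any(has)) {
    idv[has] <- num_field(idv_raw[has], path, lines[has], "idv")
    bad <- which(has & (idv < 0 | idv > 100))
    if (length(bad)) {
      stop_parse(path, lines[bad[1]], sprintf("idv %g outside [0, 100]", idv[bad[1]]))
    }
  }
  data.frame(country_id = cid, name = trimws(df$name), idv = idv,
             stringsAsFactors = FALSE)
}

#' Read a population series CSV
#'
#' @param path Path to a CSV with columns `year`, `persons`.
#' @return A year-sorted data frame with columns `year`, `persons`.
#' @export
read_population_csv <- function(path) {
  stopifnot(file.exists(path))
  parsed <- read_maybe_header(path, 2L, c("year", "persons"))
  if (is.null(parsed$df)) {
    return(data.frame(year = integer(), persons = numeric()))
  }
  df <- parsed$df
  lines <- seq_len(nrow(df)) + parsed$offset
  year <- num_field(df$year, path, lines, "year", integer = TRUE)
  persons <- num_field(df$persons, path, lines, "persons")
  bad <- which(persons <= 0)
  if (length(bad)) stop_parse(path, lines[bad[1]], "population must be positive")
  ord <- order(year)
  data.frame(year = year[ord], persons = persons[ord])
}

# Writers --------------------------------------------------------------------

#' Write a tobacco panel in the four-column CSV dialect
#'
#' @param panel A `tobacco_panel` (list of [country_series()]).
#' @param path Output path.
#' @export
write_tobacco_csv <- function(panel, path) {
  rows <- do.call(rbind, lapply(panel, function(s) {
    rbind(
      if (nrow(s$prevalence)) data.frame(country_id = s$country_id,
                                         year = s$prevalence$year,
                                         value = s$prevalence$value, flag = 0L),
      if (nrow(s$consumption)) data.frame(country_id = s$country_id,
                                          year = s$consumption$year,
                                          value = s$consumption$value, flag = 1L))
  }))
  if (is.null(rows)) rows <- data.frame(country_id = integer(), year = integer(),
                                        value = numeric(), flag = integer())
  # %.17g so that every double survives the write/read round trip bit-exactly
  lines <- c("country_id,year,value,flag",
             sprintf("%d,%d,%.17g,%d", rows$country_id, rows$year,
                     rows$value, rows$flag))
  writeLines(lines, path)
  invisible(path)
}

#' Write results losslessly as JSON
#'
#' Numeric payloads survive a write/read round trip to at least 12
#' significant digits (full double precision is written).
#'
#' @param results A list or data frame of serializable results.
#' @param path Output path (`.json`).
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back results written by [write_results()]
#'
#' @param path Path to the JSON file.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
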