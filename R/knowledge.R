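# Cumulative-knowledge proxy n(t) and the individual-utility function u_x(t).

#' Build a continuous knowledge curve from article records
#'
#' The cumulative number of scholarly articles on the health effects of
#' smoking, n(t), proxies public knowledge. Between sample years the curve is
#' piecewise-linear; before the first sample year it is 0 (no knowledge) and
#' after the last it is held at the final cumulative count.
#'
#' @param records Data frame with columns `year` and `cumulative` (as
#'   returned by [read_article_csv()]), at least one row.
#' @return An object of class `knowledge_curve`; evaluate it with
#'   [knowledge_at()] or `predict()`.
#' @export
knowledge_curve <- function(records) {
  stopifnot(is.data.frame(records), all(c("year", "cumulative") %in% names(records)))
  if (nrow(records) == 0L) stop("at least one article record is required")
  ord <- order(records$year)
  yrs <- as.numeric(records$year[ord])
  cum <- as.numeric(records$cumulative[ord])
  if (any(diff(cum) < 0)) stop("cumulative article counts must be nondecreasing")
  structure(list(years = yrs, cumulative = cum), class = "knowledge_curve")
}

#' Evaluate a knowledge curve at arbitrary (real) years
#'
#' @param curve A [knowledge_curve()].
#' @param t Numeric vector of years.
#' @return n(t), nondecreasing in `t`.
#' @export
knowledge_at <- function(curve, t) {
  stopifnot(inherits(curve, "knowledge_curve"))
  if (length(curve$years) == 1L) {
    return(ifelse(t < curve$years, 0, curve$cumulative))
  }
  stats::approx(curve$years, curve$cumulative, xout = t,
                yleft = 0, yright = curve$cumulative[length(curve$cumulative)],
                ties = "ordered")$y
}

#' @export
predict.knowledge_curve <- function(object, t, ...) knowledge_at(object, t)

#' @export
print.knowledge_curve <- function(x, ...) {
  cat(sprintf("<knowledge_curve> %d samples, %d-%d, final cumulative count %g\n",
              length(x$years), min(x$years), max(x$years),
              x$cumulative[length(x$cumulative)]))
  invisible(x)
}

#' Specify an individual-utility function
#'
#' The individual utility from smoking, u_x(t) in `[0, 1]`, declines as
#' knowledge of adverse health effects accumulates (the non-smoking utility
#' is 1 - u_x by normalization). Three functional forms are supported:
#'
#' * `"discounted"`: u_x(t) = u_inf + delta^n(t) (u_0 - u_inf), each article
#'   discounting utility by a factor `delta` in `[0, 1]`;
#' * `"step"`: u_0 before the threshold year `t_star`, u_inf from `t_star` on;
#' * `"constant"`: a single constant utility `u_const`.
#'
#' @param form One of `"discounted"`, `"step"`, `"constant"`.
#' @param u0 Limiting utility under no knowledge (discounted/step forms).
#' @param u_inf Limiting utility under saturated knowledge.
#' @param delta Per-article discount factor in `[0, 1]` (discounted form).
#' @param t_star Threshold year (step form).
#' @param u_const Constant utility (constant form).
#' @return An object of class `utility_spec`.
#' @export
utility_spec <- function(form = c("discounted", "step", "constant"),
                         u0 = NULL, u_inf = NULL, delta = NULL,
                         t_star = NULL, u_const = NULL) {
  form <- match.arg(form)
  chk01 <- function(v, nm) {
    if (is.null(v)) stop(sprintf("'%s' is required for the %s form", nm, form))
    if (!is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("'%s' must lie in [0, 1], got %g", nm, v))
    }
    v
  }
  spec <- switch(form,
    discounted = list(u0 = chk01(u0, "u0"), u_inf = chk01(u_inf, "u_inf"),
                      delta = chk01(delta, "delta")),
    step = {
      if (is.null(t_star)) stop("'t_star' is required for the step form")
      list(u0 = chk01(u0, "u0"), u_inf = chk01(u_inf, "u_inf"),
           t_star = t_star)
    },
    constant = list(u_const = chk01(u_const, "u_const")))
  structure(c(list(form = form), spec), class = "utility_spec")
}

#' @export
print.utility_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "form")]
  cat(sprintf("<utility_spec> %s: %s\n", x$form,
              paste(names(pars), signif(unlist(pars), 5), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

# delta^n computed on the log scale; 0^0 := 1 for continuity of the
# discounting interpretation, delta = 0 with n > 0 gives 0.
discount_pow <- function(delta, n) {
  if (delta == 0) return(ifelse(n == 0, 1, 0))
  exp(n * log(delta))
}

#' Evaluate the individual utility from smoking at given years
#'
#' @param spec A [utility_spec()].
#' @param t Numeric vector of years.
#' @param curve A [knowledge_curve()]; required for the discounted form.
#' @return u_x(t), values in `[0, 1]`.
#' @export
utility_value <- function(spec, t, curve = NULL) {
  stopifnot(inherits(spec, "utility_spec"))
  switch(spec$form,
    discounted = {
      if (is.null(curve)) stop("the discounted form needs a knowledge curve")
      n <- knowledge_at(curve, t)
      spec$u_inf + discount_pow(spec$delta, n) * (spec$u0 - spec$u_inf)
    },
    step = ifelse(t < spec$t_star, spec$u0, spec$u_inf),
    constant = rep_len(spec$u_const, length(t)))
}
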