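make_series <- function(years, x, c_years, c_vals, id = 1) {
  country_series(id, prevalence = data.frame(year = years, value = x),
                 consumption = data.frame(year = c_years, value = c_vals))
}

test_that("affine map is recovered exactly from exact linear data", {
  yrs <- 1960:1969
  c_vals <- seq(2, 6.5, by = 0.5)
  x_vals <- 0.05 * c_vals + 0.01
  s <- make_series(yrs, x_vals, yrs, c_vals)
  m <- fit_linear_map(s)
  expect_equal(m$C_hat, 0.05, tolerance = 1e-12)
  expect_equal(m$B_hat, 0.01, tolerance = 1e-12)
  expect_equal(m$r2, 1)
  expect_equal(m$n_obs, 10L)
})

test_that("degenerate regressions error out", {
  yrs <- 1960:1964
  s <- make_series(yrs, rep(0.3, 5), yrs, rep(2, 5))
  expect_error(fit_linear_map(s), "zero variance")
  s2 <- make_series(1960, 0.3, 1960:1964, 1:5)
  expect_error(fit_linear_map(s2), "fewer than 2")
})

test_that("map estimates on noisy synthetic overlap fall within 3 SE of truth", {
  # Monte-Carlo coverage of the OLS sampling distribution: survey noise only,
  # so classical OLS standard errors apply exactly
  set.seed(123)
  C <- 0.05; B <- 0.02; n_bad <- 0; n_rep <- 300
  c_vals <- seq(1, 8, length.out = 20)
  for (r in seq_len(n_rep)) {
    x_vals <- C * c_vals + B + rnorm(20, 0, 0.01)
    s <- make_series(1960:1979, pmin(pmax(x_vals, 0), 1), 1960:1979, c_vals)
    m <- fit_linear_map(s)
    se_C <- sqrt(sum((m$C_hat * c_vals + m$B_hat - x_vals)^2) / 18 /
                   sum((c_vals - mean(c_vals))^2))
    if (abs(m$C_hat - C) > 3 * se_C) n_bad <- n_bad + 1
  }
  expect_lt(n_bad / n_rep, 0.01 + 3 * sqrt(0.01 * 0.99 / n_rep))
})

test_that("Grubbs screening flags a single gross outlier", {
  # closed-form critical value computed independently in the test
  yrs <- 1960:1964
  c_vals <- c(2, 2, 2, 2, 2.0001)
  x_vals <- c(0.1, 0.1, 0.1, 0.1, 0.5)  # ratio pattern {1,1,1,1,5}
  s <- make_series(yrs, x_vals, yrs, c_vals)
  map <- structure(list(country_id = 1L, C_hat = 0, B_hat = 0.1, r2 = 1,
                        p = 0, n_obs = 5L, years = yrs,
                        excluded = integer()), class = "linear_map")
  flagged <- grubbs_screen(s, map, alpha = 0.05)
  expect_equal(flagged$year, 1964L)
  n <- 5
  tq <- qt(0.05 / (2 * n), df = n - 2, lower.tail = FALSE)
  g_crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  ratios <- x_vals / 0.1
  g_obs <- max(abs(ratios - mean(ratios))) / sd(ratios)
  expect_gt(g_obs, g_crit)
  expect_lt(flagged$p, 0.05)
})

test_that("Grubbs screening is quiet on constant ratios and needs n >= 3", {
  yrs <- 1960:1963
  s <- make_series(yrs, c(0.1, 0.2, 0.3, 0.4), yrs, c(1, 2, 3, 4))
  map <- fit_linear_map(s)
  expect_equal(nrow(grubbs_screen(s, map)), 0L)
  s2 <- make_series(1960:1961, c(0.1, 0.2), 1960:1961, c(1, 2))
  expect_error(grubbs_screen(s2, map), "at least 3")
})

test_that("an injected inconsistent survey spike is flagged and its removal raises R2", {
  set.seed(0)
  yrs <- 1950:1975
  c_vals <- 2 + 0.15 * (yrs - 1950) + rnorm(length(yrs), 0, 0.05)
  x_vals <- 0.05 * c_vals + 0.02 + rnorm(length(yrs), 0, 0.005)
  x_vals[11] <- 0.32  # far off the affine relationship, like a bad survey
  s <- make_series(yrs, pmin(pmax(x_vals, 0), 1), yrs, c_vals)
  m0 <- fit_linear_map(s)
  flagged <- grubbs_screen(s, m0)
  expect_equal(flagged$year, yrs[11])
  m1 <- fit_linear_map(s, exclude_years = flagged$year)
  expect_gt(m1$r2, m0$r2)
})

test_that("inclusion filter uses >=, <, >= boundary semantics and is monotone", {
  mk <- function(id, r2, p, n) {
    structure(list(country_id = id, C_hat = 1, B_hat = 0, r2 = r2, p = p,
                   n_obs = n, years = integer(), excluded = integer()),
              class = "linear_map")
  }
  maps <- list(mk(1, 0.69, 1e-5, 20),   # fails R2 (strict >=)
               mk(2, 0.7, 1e-5, 15),    # boundary: included
               mk(3, 0.9, 0.001, 20),   # fails p (strict <)
               mk(4, 0.9, 1e-9, 14))    # fails n_obs
  expect_equal(select_countries(maps), 2L)
  loose <- select_countries(maps, r2_min = 0.5, p_max = 0.01, n_min = 10)
  expect_true(all(2L %in% loose) && length(loose) >= 1)
  expect_true(all(select_countries(maps) %in% loose))
  expect_warning(select_countries(maps, r2_min = 1.1), "no country")
})

test_that("prevalence estimation is the exact affine map, unclamped", {
  yrs <- 1930:1934
  s <- make_series(1960, 0.1, yrs, c(0, 2, 4, 20, 1))
  map <- structure(list(country_id = 1L, C_hat = 0.05, B_hat = 0.02, r2 = 1,
                        p = 0, n_obs = 10L, years = yrs,
                        excluded = integer()), class = "linear_map")
  est <- estimate_prevalence(s, map)
  expect_equal(est$x_hat, c(0.02, 0.12, 0.22, 1.02, 0.07))  # >1 kept as-is
  # affine equivariance: scaling consumption scales the estimate exactly
  s2 <- make_series(1960, 0.1, yrs, 2 * c(0, 2, 4, 20, 1))
  est2 <- estimate_prevalence(s2, map)
  expect_equal(est2$x_hat - map$B_hat, 2 * (est$x_hat - map$B_hat))
})

test_that("noise-free generator round-trips through map fitting and estimation", {
  sp <- synth_panel(2, seed = 3, sigma_x = 0, sigma_c = 0)
  for (k in names(sp$panel)) {
    m <- fit_linear_map(sp$panel[[k]])
    truth <- sp$truth[sp$truth$country_id == as.integer(k), ]
    expect_equal(m$C_hat, truth$C, tolerance = 1e-8)
    expect_equal(m$B_hat, truth$B, tolerance = 1e-8)
    expect_equal(m$r2, 1, tolerance = 1e-10)
    est <- estimate_prevalence(sp$panel[[k]], m)
    expect_equal(est$x_hat, attr(sp$panel[[k]], "truth")$x, tolerance = 1e-7)
  }
})
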