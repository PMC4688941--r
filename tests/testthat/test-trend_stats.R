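test_that("peak year takes the earliest argmax and ignores scaling", {
  s <- data.frame(year = c(1950, 1960, 1970, 1980), value = c(1, 5, 5, 2))
  expect_equal(peak_year(s), 1960)
  expect_equal(peak_year(transform(s, value = 3.7 * value)), 1960)
  inc <- data.frame(year = 1950:1960, value = 1:11)
  expect_equal(peak_year(inc), 1960)
  expect_error(peak_year(data.frame(year = integer(), value = numeric())),
               "empty")
})

test_that("average slope is the endpoint difference quotient, no interpolation", {
  xh <- data.frame(year = c(1920, 1950, 1963), x_hat = c(0.05, 0.2, 0.40))
  expect_equal(average_slope(xh, 1963), 0.35 / 43)
  flat <- data.frame(year = c(1920, 1963), x_hat = c(0.3, 0.3))
  expect_equal(average_slope(flat, 1963), 0)
  expect_error(average_slope(xh, 1920), "undefined")
  expect_error(average_slope(xh, 1955), "t_max")      # year not present
  expect_error(average_slope(xh[-1, ], 1963), "t0")   # 1920 missing
  # antisymmetry under swapping the endpoint values
  sw <- data.frame(year = c(1920, 1950, 1963), x_hat = c(0.40, 0.2, 0.05))
  expect_equal(average_slope(sw, 1963), -average_slope(xh, 1963))
})

test_that("pearson_correlation matches the covariance-formula oracle", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- pearson_correlation(x, y)
    rho_direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r$rho, rho_direct, tolerance = 1e-12)
    tstat <- rho_direct * sqrt((n - 2) / (1 - rho_direct^2))
    expect_equal(r$p, 2 * pt(abs(tstat), n - 2, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(r$slope, cov(x, y) / var(x), tolerance = 1e-12)
  }
  expect_equal(pearson_correlation(1:5, 1:5)$rho, 1)
  expect_equal(pearson_correlation(1:5, -2 * (1:5) + 3)$rho, -1)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("trend_correlations returns the analysis pairs as a tidy table", {
  df <- data.frame(a = c(1.1, 1.0, 0.95, 1.05), idv = c(20, 60, 85, 40),
                   s_x = c(0.004, 0.006, 0.008, 0.005),
                   t_max = c(1980, 1970, 1963, 1975))
  tab <- trend_correlations(df)
  expect_setequal(paste(tab$x, tab$y),
                  c("idv a", "idv s_x", "idv t_max", "a s_x", "a t_max"))
  expect_true(all(tab$n == 4))
  expect_lt(tab$rho[tab$x == "idv" & tab$y == "a"], 0)
})

test_that("counterfactual is null at zero IDV shift and positive for a reduction", {
  sp <- synth_panel(1, seed = 15, sigma_x = 0, sigma_c = 0)
  curve <- knowledge_curve(sp$articles)
  m <- fit_linear_map(sp$panel[[1]])
  xh <- list(one = estimate_prevalence(sp$panel[[1]], m))
  fit <- fit_smoking_model(xh, curve, config = fit_config(max_itn = 2))
  pop <- data.frame(year = seq(1920, 2010, by = 10),
                    persons = seq(100e6, 300e6, length.out = 10))
  base <- counterfactual_consumption(fit, "one", m, a_idv_slope = -5.6e-3,
                                     idv = 80, delta_idv_pct = 0,
                                     population = pop)
  expect_equal(base$percent_decrease, 0)
  cf <- counterfactual_consumption(fit, "one", m, a_idv_slope = -5.6e-3,
                                   idv = 80, delta_idv_pct = 2,
                                   population = pop)
  # lower IDV -> higher conformity -> slower adoption -> fewer cigarettes
  expect_gt(cf$a_counterfactual, cf$a_baseline)
  expect_gt(cf$percent_decrease, 0)
  short_pop <- pop[pop$year >= 1950, ]
  expect_error(counterfactual_consumption(fit, "one", m, -5.6e-3, 80, 2,
                                          short_pop),
               "cover")
})
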