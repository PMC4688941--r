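# A small noise-free two-country panel shared across the tests below.
shared <- local({
  curve <- fixture_curve()
  c1 <- fixture_xhat(a = 1.05, x0 = 0.12, u0 = 0.55, u_inf = 0.49,
                     years = 1920:2000, curve = curve)
  c2 <- fixture_xhat(a = 0.95, x0 = 0.08, u0 = 0.53, u_inf = 0.48,
                     years = 1920:2000, curve = curve)
  list(curve = curve,
       xhat = list(alpha = c1$xhat, beta = c2$xhat),
       truth = list(alpha = c1$truth, beta = c2$truth))
})

test_that("error norms match direct arithmetic oracles", {
  fx <- fixture_xhat(years = 1950:1970)
  locals <- c(a = fx$truth$a, x0 = fx$truth$x0, u0 = fx$truth$u0,
              u_inf = fx$truth$u_inf)
  universals <- c(b = fx$truth$b, delta = fx$truth$delta)
  # prediction == data: both norms vanish
  expect_lt(local_error(fx$xhat, locals, universals, fx$curve), 1e-14)
  expect_lt(mean_abs_error(fx$xhat, locals, universals, fx$curve), 1e-8)
  # shift the data by a known residual vector; compare to direct sums
  set.seed(21)
  r <- rnorm(nrow(fx$xhat), 0, 0.05)
  shifted <- fx$xhat
  shifted$x_hat <- shifted$x_hat - r
  expect_equal(local_error(shifted, locals, universals, fx$curve),
               sum(r^2), tolerance = 1e-10)
  expect_equal(mean_abs_error(shifted, locals, universals, fx$curve),
               mean(abs(r)), tolerance = 1e-10)
  # single-observation residual of 0.1 gives E2 = 0.01; {0.1, -0.3} -> E1 0.2
  one <- fx$xhat[1, ]
  one$x_hat <- one$x_hat - 0.1
  expect_equal(local_error(one, locals, universals, fx$curve), 0.01,
               tolerance = 1e-10)
  two <- fx$xhat[1:2, ]
  two$x_hat <- two$x_hat - c(0.1, -0.3)
  expect_equal(mean_abs_error(two, locals, universals, fx$curve), 0.2,
               tolerance = 1e-9)
})

test_that("country_fit recovers the generating locals from noise-free data", {
  fx <- fixture_xhat(a = 1.08, x0 = 0.15, u0 = 0.56, u_inf = 0.49,
                     years = 1920:2012)
  res <- country_fit(fx$xhat, c(b = fx$truth$b, delta = fx$truth$delta),
                     fx$curve, fit_config())
  expect_lt(abs(res$par[["a"]] - fx$truth$a), 1e-3)
  expect_lt(abs(res$par[["x0"]] - fx$truth$x0), 1e-3)
  expect_lt(abs(res$par[["u0"]] - fx$truth$u0), 5e-3)
  expect_lt(abs(res$par[["u_inf"]] - fx$truth$u_inf), 5e-3)
  expect_lt(res$E2, 1e-8)
})

test_that("a flat series under the null field is fitted exactly", {
  xh <- data.frame(year = 1950:1990, x_hat = rep(0.27, 41))
  res <- country_fit(xh, c(b = 1), form = "constant", config = fit_config())
  expect_lt(res$E2, 1e-10)
})

test_that("data demanding a steeper conformity than allowed pins a at its bound", {
  spec <- utility_spec("constant", u_const = 0.6)
  tr <- simulate_prevalence(a = 2, b = 2, x0 = 0.5, t0 = 1950, spec = spec,
                            years = 1950:2000)
  xh <- data.frame(year = tr$year, x_hat = tr$x)
  res <- country_fit(xh, c(b = 1), form = "constant", config = fit_config())
  expect_equal(res$par[["a"]], 2)
})

test_that("universal_fit recovers (b, delta) with locals held at truth", {
  fx <- fixture_xhat(a = 1.05, x0 = 0.12, u0 = 0.55, u_inf = 0.49,
                     years = 1920:2012)
  locals <- c(a = fx$truth$a, x0 = fx$truth$x0, u0 = fx$truth$u0,
              u_inf = fx$truth$u_inf)
  res <- universal_fit(list(s = fx$xhat), list(s = locals),
                       c(b = 1, delta = 0.9985), fx$curve, fit_config())
  expect_lt(abs(res$par[["b"]] - fx$truth$b), 1e-3)
  expect_lt(abs(res$par[["delta"]] - fx$truth$delta), 1e-4)
  # starting at the optimum cannot worsen the objective
  at_truth <- universal_fit(list(s = fx$xhat), list(s = locals),
                            c(b = fx$truth$b, delta = fx$truth$delta),
                            fx$curve, fit_config())
  expect_lte(at_truth$E2, res$E2 + 1e-12)
  # duplicating the country leaves the optimum unchanged (objective scales by 2)
  dup <- universal_fit(list(s = fx$xhat, s2 = fx$xhat),
                       list(s = locals, s2 = locals),
                       c(b = 1, delta = 0.9985), fx$curve, fit_config())
  expect_equal(dup$par[["b"]], res$par[["b"]], tolerance = 1e-6)
  expect_equal(dup$par[["delta"]], res$par[["delta"]], tolerance = 1e-6)
})

test_that("the iteration cap bounds the alternation exactly", {
  cfg <- fit_config(max_itn = 1, joint_refine = FALSE)
  fit <- fit_smoking_model(shared$xhat["alpha"], shared$curve, config = cfg)
  expect_identical(fit$iterations, 1L)
  expect_length(fit$E2_history, 1L)
})

test_that("alternation drives E_2 monotonically down and the refinement below 1e-6", {
  fit <- fit_smoking_model(shared$xhat, shared$curve,
                           config = fit_config(max_itn = 3))
  expect_true(all(diff(fit$E2_history) <= 1e-10))
  expect_lt(fit$E2, 1e-6)
  expect_equal(fit$E2, sum(fit$locals$E_i2), tolerance = 1e-12)
  # locals and universals recovered
  expect_lt(abs(fit$universals[["b"]] - 1.049), 1e-3)
  expect_lt(abs(fit$universals[["delta"]] - 0.9981), 1e-4)
  for (k in names(shared$xhat)) {
    expect_lt(abs(fit$locals_list[[k]][["a"]] - shared$truth[[k]]$a), 1e-3)
  }
})

test_that("constant-utility data is fitted equally well by the nesting discounted form", {
  spec <- utility_spec("constant", u_const = 0.56)
  tr <- simulate_prevalence(a = 1.05, b = 1.049, x0 = 0.12, t0 = 1940,
                            spec = spec, years = 1940:2000)
  xh <- list(k = data.frame(year = tr$year, x_hat = tr$x))
  cfg <- fit_config(max_itn = 2, inner_maxiter = 30)
  f_const <- fit_smoking_model(xh, form = "constant", config = cfg)
  f_disc <- fit_smoking_model(xh, shared$curve, form = "discounted",
                              config = cfg)
  # truth lies in both families (delta = 1 reduces discounted to constant)
  expect_lt(f_const$E2, 1e-8)
  expect_lt(f_disc$E2, f_const$E2 + 1e-6)
})

test_that("two runs with identical data and config agree bitwise", {
  cfg <- fit_config(max_itn = 2, joint_refine = FALSE)
  f1 <- fit_smoking_model(shared$xhat, shared$curve, config = cfg)
  f2 <- fit_smoking_model(shared$xhat, shared$curve, config = cfg)
  expect_identical(f1$universals, f2$universals)
  expect_identical(f1$locals_list, f2$locals_list)
  expect_identical(f1$E2, f2$E2)
})

test_that("fit methods expose parameters, predictions and residuals coherently", {
  cfg <- fit_config(max_itn = 1, joint_refine = FALSE)
  fit <- fit_smoking_model(shared$xhat, shared$curve, config = cfg)
  cf <- coef(fit)
  expect_true(all(c("b", "delta", "a.alpha", "x0.beta") %in% names(cf)))
  expect_identical(coef(fit, "universal"), fit$universals)
  pred <- predict(fit)
  expect_equal(nrow(pred), sum(vapply(shared$xhat, nrow, integer(1))))
  res <- residuals(fit)
  expect_equal(sum(res$residual^2), fit$E2, tolerance = 1e-10)
  expect_output(print(fit), "universal parameters")
  expect_output(print(summary(fit)), "Local parameters")
  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp)
  expect_silent(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(tmp))
})
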