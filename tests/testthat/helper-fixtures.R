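# Shared fixtures, built in code at test time.

# Deterministic article curve (no Poisson jitter) for fast utility tests.
fixture_curve <- function() {
  knowledge_curve(synth_articles(jitter = FALSE))
}

# A small estimated-prevalence series generated by the model itself, for
# calibration subproblem tests. Returns the series plus the generating truth.
fixture_xhat <- function(a = 1.05, b = 1.049, x0 = 0.1, u0 = 0.54,
                         u_inf = 0.49, delta = 0.9981, years = 1920:2000,
                         curve = fixture_curve()) {
  spec <- utility_spec("discounted", u0 = u0, u_inf = u_inf, delta = delta)
  traj <- simulate_prevalence(a, b, x0, years[1], spec, years, curve)
  list(xhat = data.frame(year = traj$year, x_hat = traj$x),
       truth = list(a = a, b = b, x0 = x0, u0 = u0, u_inf = u_inf,
                    delta = delta),
       curve = curve)
}

# Classic fixed-step RK4 integrator, independent of the deSolve-based path.
rk4_oracle <- function(a, b, x0, t0, t_end, u_fun, dt = 1e-3) {
  f <- function(t, x) {
    x <- min(max(x, 0), 1)
    b * ((1 - x) * x^a * u_fun(t) - x * (1 - x)^a * (1 - u_fun(t)))
  }
  n <- round((t_end - t0) / dt)
  x <- x0
  t <- t0
  for (i in seq_len(n)) {
    k1 <- f(t, x)
    k2 <- f(t + dt / 2, x + dt * k1 / 2)
    k3 <- f(t + dt / 2, x + dt * k2 / 2)
    k4 <- f(t + dt, x + dt * k3)
    x <- x + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    t <- t + dt
  }
  x
}

# Write a minimal tobacco CSV from raw rows (country, year, value, flag).
write_rows <- function(rows, path, header = FALSE) {
  lines <- apply(rows, 1, paste, collapse = ",")
  if (header) lines <- c("country_id,year,value,flag", lines)
  writeLines(lines, path)
  path
}
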