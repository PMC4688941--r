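test_that("tobacco CSV rows map to typed records in the stated column order", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_rows(rbind(c(3, 1965, 0.25, 0), c(3, 1960, 3.6, 1),
                   c(1, 1970, 0.30, 0)), p)
  panel <- read_tobacco_csv(p)
  expect_s3_class(panel, "tobacco_panel")
  expect_named(panel, c("1", "3"))
  expect_equal(panel[["3"]]$prevalence,
               data.frame(year = 1965L, value = 0.25))
  expect_equal(panel[["3"]]$consumption,
               data.frame(year = 1960L, value = 3.6))
})

test_that("tobacco CSV header detection and empty files behave", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_rows(rbind(c(2, 1950, 1.25, 1)), p, header = TRUE)
  panel <- read_tobacco_csv(p)
  expect_equal(panel[["2"]]$consumption$value, 1.25)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), empty)
  expect_warning(out <- read_tobacco_csv(empty), "no tobacco records")
  expect_length(out, 0)
})

test_that("tobacco ingest rejects rather than repairs", {
  bad_flag <- withr::local_tempfile(fileext = ".csv")
  write_rows(rbind(c(1, 1950, 0.2, 2)), bad_flag)
  expect_error(read_tobacco_csv(bad_flag), "type flag must be 0 or 1")

  pct <- withr::local_tempfile(fileext = ".csv")
  write_rows(rbind(c(1, 1950, 25, 0)), pct)
  expect_error(read_tobacco_csv(pct), "not a fraction")

  dup <- withr::local_tempfile(fileext = ".csv")
  write_rows(rbind(c(1, 1950, 0.2, 0), c(1, 1950, 0.3, 0)), dup)
  expect_error(read_tobacco_csv(dup), "duplicate")

  malformed <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,1950,0.2,0", "1,19x0,0.3,0"), malformed)
  expect_error(read_tobacco_csv(malformed), "line 2")

  bad_year <- withr::local_tempfile(fileext = ".csv")
  write_rows(rbind(c(1, 1700, 0.2, 0)), bad_year)
  expect_error(read_tobacco_csv(bad_year), "outside \\[1850, 2100\\]")
})

test_that("article CSV enforces cumulative consistency", {
  ok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1950,10,100", "1951,5,105"), ok)
  rec <- read_article_csv(ok)
  expect_equal(rec$cumulative, c(100L, 105L))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1950,10,100", "1951,5,90"), bad)
  expect_error(read_article_csv(bad), "cumulative")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1950,-1,100"), neg)
  expect_error(read_article_csv(neg), "negative")

  single <- withr::local_tempfile(fileext = ".csv")
  writeLines("1900,0,0", single)
  expect_equal(nrow(read_article_csv(single)), 1L)
})

test_that("country registry stores absent IDV as NA and rejects duplicates", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,Australia,90", "2,Nowhere,"), p)
  reg <- read_country_table(p)
  expect_equal(reg$name, c("Australia", "Nowhere"))
  expect_equal(reg$idv, c(90, NA))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,A,10", "1,B,20"), dup)
  expect_error(read_country_table(dup), "duplicate country id")
})

test_that("write/read round trip reproduces a panel field-for-field", {
  sp <- synth_panel(2, seed = 7)
  p <- withr::local_tempfile(fileext = ".csv")
  write_tobacco_csv(sp$panel, p)
  back <- read_tobacco_csv(p)
  expect_equal(length(back), length(sp$panel))
  for (k in names(sp$panel)) {
    expect_equal(back[[k]]$prevalence$value, sp$panel[[k]]$prevalence$value)
    expect_equal(back[[k]]$consumption$value, sp$panel[[k]]$consumption$value)
    expect_identical(back[[k]]$prevalence$year, sp$panel[[k]]$prevalence$year)
  }
})

test_that("results JSON round-trips numeric payloads at full precision", {
  res <- list(universals = list(b = 1.0489999999912, delta = 0.99810000000017),
              E2 = 0.16300000000123)
  p <- withr::local_tempfile(fileext = ".json")
  write_results(res, p)
  back <- read_results(p)
  expect_equal(back$universals$b, res$universals$b, tolerance = 1e-12)
  expect_equal(back$E2, res$E2, tolerance = 1e-12)
})
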