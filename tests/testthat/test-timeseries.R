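test_that("CSV parsing handles missing cells, sorting and validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,month,value", "2001,5,1.2", "2001,6,NA", "2001,7,0.8"),
             path)
  x <- read_series(path, variable = "phytoplankton")
  expect_equal(nrow(x), 3)
  expect_equal(is.na(x$value), c(FALSE, TRUE, FALSE))

  writeLines(c("year,month,value", "2001,6,1.0", "2001,5,1.0"), path)
  x <- read_series(path, variable = "phytoplankton")
  expect_equal(x$month, c(5L, 6L))

  writeLines(c("year,month,value", "2001,5,-1.0"), path)
  expect_error(read_series(path, variable = "phytoplankton"), "> 0")

  writeLines(c("year,month,value", "2001,5,1.0", "2001,5,2.0"), path)
  expect_error(read_series(path, variable = "phytoplankton"), "duplicate")

  writeLines(c("year,month,value", "2001,5,1.0", "2001,6,oops"), path)
  expect_error(read_series(path, variable = "phytoplankton"), "row 2")
})

test_that("season runs split at gaps of one calendar month or more", {
  two_seasons <- mk_series(rep(1, 12))
  r <- season_runs(two_seasons)
  expect_equal(r$start, c(1L, 7L))
  expect_equal(r$end, c(6L, 12L))

  one <- mk_series(rep(1, 6))
  expect_equal(season_runs(one)[, c("start", "end")],
               data.frame(start = 1L, end = 6L))

  # May, June, August: July absent from the record entirely
  x <- monitoring_series(2001, c(5, 6, 8), c(1, 1, 1),
                         variable = "phytoplankton")
  r <- season_runs(x)
  expect_equal(r$start, c(1L, 3L))
  expect_equal(r$end, c(2L, 3L))
})

test_that("season runs partition the sample indices", {
  set.seed(11)
  for (i in 1:20) {
    months <- sort(sample(1:12, sample(3:12, 1)))
    yrs <- sample(1:3, 1)
    x <- monitoring_series(rep(2000 + seq_len(yrs), each = length(months)),
                           rep(months, yrs), 1,
                           variable = "temperature")
    r <- season_runs(x)
    expect_equal(sum(r$length), nrow(x))
    expect_equal(unlist(Map(seq, r$start, r$end), use.names = FALSE),
                 seq_len(nrow(x)))
  }
})

test_that("alignment restricts both series to common timestamps", {
  a <- mk_series(1:12)
  al <- align_series(a, a)
  expect_equal(al$a$value, a$value)
  expect_equal(al$b$month, a$month)

  b <- monitoring_series(rep(2002:2003, each = 6), rep(5:10, 2), 1:12,
                         variable = "zooplankton")
  al <- align_series(a, b)
  expect_equal(al$a$year, rep(2002L, 6))
  expect_equal(al$a$year, al$b$year)
  expect_equal(al$a$month, al$b$month)
  expect_equal(al$a$value, 7:12)
  expect_equal(al$b$value, 1:6)

  c_ <- monitoring_series(2010, 5:7, 1:3, variable = "temperature")
  expect_error(align_series(a, c_), "common")
})

test_that("write/read round-trips monitoring and derived series", {
  set.seed(21)
  for (i in 1:10) {
    x <- mk_series(round(stats::runif(12, 0.1, 9), 3))
    x$value[sample(12, 2)] <- NA
    path <- withr::local_tempfile(fileext = ".csv")
    write_series(x, path)
    y <- read_series(path, variable = "phytoplankton")
    expect_equal(y$value, x$value)
    expect_equal(y$year, x$year)
    expect_equal(y$month, x$month)
  }

  sim <- forward_simulate(sim_spec(n_years = 2, seed = 3))
  G <- growth_rate(sim$P, sim$Z, sim$spec$params)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(G, path)
  df <- utils::read.csv(path)
  expect_named(df, c("year", "month", "value", "run_id"))
  expect_equal(df$value, G$value)
})
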