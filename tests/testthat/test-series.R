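test_that("FTD pools catches over traps and exposure days", {
  obs <- trap_obs("A", "2010-06-01", "2010-06-15", n_traps = 3,
                  total_catch = 42)
  expect_equal(compute_ftd(obs), 1.0)

  zero <- trap_obs("A", "2010-06-01", "2010-06-15", 3, 0)
  expect_equal(compute_ftd(zero), 0.0)

  # two collection rounds with different exposures: totals over trap-days
  rounds <- trap_obs("A", c("2010-06-01", "2010-06-16"),
                     c("2010-06-16", "2010-07-02"),
                     n_traps = c(2, 2), total_catch = c(30, 0))
  expect_equal(compute_ftd(rounds), 30 / 62)

  # invariant to splitting a round into sub-rounds with identical totals
  split_rounds <- trap_obs("A",
                           c("2010-06-01", "2010-06-08", "2010-06-16", "2010-06-16"),
                           c("2010-06-08", "2010-06-16", "2010-06-24", "2010-07-02"),
                           n_traps = c(2, 2, 2, 1),
                           total_catch = c(10, 20, 0, 0))
  # same trap-days? 2*7 + 2*8 + 2*8 + 1*16 = 62, same total catch 30
  expect_equal(compute_ftd(split_rounds), 30 / 62)
})

test_that("trap observation validation rejects impossible rounds", {
  expect_error(trap_obs("A", "2010-06-15", "2010-06-01", 3, 5), "period_end")
  expect_error(trap_obs("A", "2010-06-01", "2010-06-15", 0, 5), "n_traps")
  expect_error(trap_obs("A", "2010-06-01", "2010-06-15", 3, -1), "non-negative")
  expect_error(trap_obs("A", "2010-06-01", "2010-06-15", 3, 5,
                        females = 4, males = 3), "exceed")
})

test_that("monthly abundance and MFT transform match their definitions", {
  expect_equal(monthly_abundance(1.0, 30), 30.0)
  expect_equal(monthly_abundance(0, 31), 0)
  expect_equal(monthly_abundance(0.82, 28), 22.96)
  expect_error(monthly_abundance(-0.1, 30), "non-negative")
  expect_error(monthly_abundance(1, 27), "28..31")

  expect_equal(mft_transform(0), 0)
  expect_equal(mft_transform(exp(1) - 1), 1)
  expect_equal(mft_transform(30), log(31))
  expect_error(mft_transform(-2), "non-negative")

  # strictly increasing, and the inverse recovers counts
  x <- c(0, 0.3, 5, 122.7, 9000)
  m <- mft_transform(x)
  expect_true(all(diff(m) > 0))
  expect_equal(exp(m) - 1, x, tolerance = 1e-12)
})

test_that("population series enforces calendar and value invariants", {
  s <- population_series("A", c("2010-01", "2010-02", "2010-03"),
                         ftd = c(1, NA, 0), nlst = c(10, 11, 12),
                         naoi = c(0.1, -0.2, 0), fruit = c(1, 1, 0))
  expect_s3_class(s, "population_series")
  expect_equal(s$days, c(31, 28, 31))
  expect_equal(s$mft, log(s$monthly_count + 1))
  expect_true(is.na(s$mft[2]))
  expect_equal(s$mft[3], 0) # observed month, zero catch

  expect_error(population_series("A", c("2010-01", "2010-01"), c(1, 2)),
               "duplicated")
  expect_error(population_series("A", c("2010-02", "2010-01"), c(1, 2)),
               "increasing")
  expect_error(population_series("A", "2010-01", -1), "non-negative")
  expect_error(population_series("A", "2010-01", 1, fruit = 2), "fruit")

  # leap awareness
  expect_equal(population_series("A", "2012-02", 1)$days, 29)
})

test_that("series CSV round-trips losslessly and keeps NA distinct from 0", {
  s <- population_series("A", c("2010-01", "2010-02", "2010-04"),
                         ftd = c(1.25, NA, 0), nlst = c(10.5, NA, 12),
                         naoi = c(0.1, -0.2, NA), fruit = c(1, NA, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(s, path)
  s2 <- read_series(path)
  expect_equal(as.data.frame(s2), as.data.frame(s))
  expect_true(is.na(s2$ftd[2]))
  expect_false(identical(s2$ftd[2], 0))

  # unknown columns are refused with a descriptive error
  d <- read.csv(path)
  d$bogus <- 1
  write.csv(d, path, row.names = FALSE)
  expect_error(read_series(path), "bogus")
})

test_that("multi-site files split per site and mft recomputes from ftd x days", {
  s1 <- population_series("A", c("2011-01", "2011-02"), c(1, 2),
                          nlst = c(8, 9), naoi = c(0, 0), fruit = c(0, 0))
  s2 <- population_series("B", c("2011-01", "2011-02"), c(3, 4),
                          nlst = c(10, 11), naoi = c(0, 0), fruit = c(1, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  both <- rbind(as.data.frame(s1), as.data.frame(s2))
  write.csv(data.frame(site = both$site, month = format(both$month, "%Y-%m"),
                       ftd = both$ftd, days = both$days, fruit = both$fruit,
                       nlst = both$nlst, naoi = both$naoi),
            path, row.names = FALSE)
  lst <- read_series(path)
  expect_named(lst, c("A", "B"))
  expect_equal(lst$B$mft, log(lst$B$ftd * lst$B$days + 1))
  one <- read_series(path, site = "B")
  expect_s3_class(one, "population_series")
})

test_that("raw trap rounds aggregate into months by majority of exposure", {
  # round spanning a month boundary: 2010-06-25..2010-07-10 has 6 June days
  # and 9 July days -> assigned to July
  obs <- trap_obs("A",
                  c("2010-06-01", "2010-06-25", "2010-07-10"),
                  c("2010-06-25", "2010-07-10", "2010-07-28"),
                  n_traps = c(4, 4, 4), total_catch = c(48, 30, 36))
  s <- series_from_trap_obs(obs)
  expect_equal(format(s$month, "%Y-%m"), c("2010-06", "2010-07"))
  expect_equal(s$ftd[1], 48 / (4 * 24))
  expect_equal(s$ftd[2], (30 + 36) / (4 * 15 + 4 * 18))

  # raw CSV reader produces the same series
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(site = "A",
                       start = c("2010-06-01", "2010-06-25", "2010-07-10"),
                       end = c("2010-06-25", "2010-07-10", "2010-07-28"),
                       n_traps = 4, catch = c(48, 30, 36)),
            path, row.names = FALSE)
  s2 <- read_series(path, format = "raw")
  expect_equal(s2$ftd, s$ftd)
})

test_that("season map covers all months with four seasons", {
  ss <- season_of(1:12)
  expect_equal(nlevels(ss), 4)
  expect_false(anyNA(ss))
  expect_equal(as.character(season_of(c(12, 3, 6, 9))),
               c("DJF", "MAM", "JJA", "SON"))
})

test_that("series_stats summarises observed FTD values", {
  s <- population_series("A", c("2010-01", "2010-02", "2010-03", "2010-04"),
                         ftd = c(1, 3, NA, 0))
  st <- series_stats(s)
  expect_equal(st$mean_ftd, mean(c(1, 3, 0)))
  expect_equal(st$sd_ftd, sd(c(1, 3, 0)))
  expect_equal(st$max_ftd, 3)
  expect_equal(st$months, 3)
  expect_equal(st$zero_capture_months, 1)
})
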