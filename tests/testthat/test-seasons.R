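flat_curve <- function(values) {
  tibble::tibble(doy = seq_along(values), fit = values)
}

test_that("crossings are found by linear interpolation on the closed DOY circle", {
  # everywhere above the level: no crossings
  expect_equal(nrow(find_crossings(flat_curve(rep(1, 366)), 0)), 0)

  # piecewise-linear toy: values -1 at DOY <= 10, +1 from DOY 11 on; level 0
  v <- c(rep(-1, 10), rep(1, 356))
  cr <- find_crossings(flat_curve(v), 0)
  up <- cr[cr$direction == "upward", ]
  expect_equal(up$doy, 10.5)
  # the wrap edge 366 -> 1 also crosses (downward)
  down <- cr[cr$direction == "downward", ]
  expect_equal(nrow(down), 1)
  expect_gt(down$doy, 366)
  # a pure sinusoid about its own mean: exactly 2 crossings half a period apart
  s <- sin(2 * pi * (1:366) / 366)
  cr2 <- find_crossings(flat_curve(s), 0)
  expect_equal(nrow(cr2), 2)
  expect_equal(circ_doy_dist(cr2$doy[1], cr2$doy[2]), 183, tolerance = 0.01)
})

test_that("crossings cluster by single linkage on the circle", {
  one <- cluster_transitions(tibble::tibble(doy = 150), gap_max = 20)
  expect_equal(one$start, 150)
  expect_equal(one$n_crossings, 1L)

  p <- cluster_transitions(tibble::tibble(doy = c(100, 103, 250)), gap_max = 20)
  expect_equal(nrow(p), 2)
  expect_equal(p$start, c(100, 250))
  expect_equal(p$end, c(103, 250))

  # wrap: {363, 2} at circular distance 5 forms one period across New Year
  w <- cluster_transitions(tibble::tibble(doy = c(363, 2)), gap_max = 20)
  expect_equal(nrow(w), 1)
  expect_equal(w$start, 363)
  expect_equal(w$end, 2)
  expect_equal(w$n_crossings, 2L)
})

test_that("boundaries are period medians and seasons tile the year", {
  periods <- tibble::tibble(
    period_id = 1:3, start = c(100, 192, 275), end = c(103, 192, 275),
    n_crossings = c(3L, 1L, 1L),
    crossings = list(c(100, 101, 103), 192, 275)
  )
  # curve: above level between 101 and 191, below elsewhere (values irrelevant
  # beyond sign for the persistence check)
  v <- ifelse(1:366 > 101 & 1:366 <= 191, 1, -1)
  out <- season_boundaries(periods, flat_curve(v), 0, persistence = 0)
  expect_equal(out$boundaries, c(101, 192, 275))
  expect_equal(sum(out$seasons$length_days), 365)
  expect_equal(sum(out$seasons$length_days_leap), 366)

  expect_error(
    season_boundaries(periods[1, ], flat_curve(v), 0),
    "fewer than 2"
  )

  # persistence violation warns and names the interval: a long
  # wrong-signed stretch inside the third season only
  wob <- rep(1, 366)
  wob[300:340] <- -1
  expect_warning(
    season_boundaries(periods, flat_curve(wob), 0, persistence = 0.9),
    "not persistently"
  )
})

test_that("season lengths match the published season calendar", {
  expect_equal(season_lengths("Mar 13", "Jul 10"), 120)
  expect_equal(season_lengths("Jul 11", "Oct 1"), 83)
  expect_equal(season_lengths("Oct 2", "Mar 12"), 162)
  expect_equal(season_lengths("Oct 2", "Mar 12", leap = TRUE), 163)
  expect_equal(
    season_lengths("Mar 13", "Jul 10") + season_lengths("Jul 11", "Oct 1") +
      season_lengths("Oct 2", "Mar 12"),
    365
  )
  # numeric DOYs and Dates are accepted
  expect_equal(season_lengths(72, 191), 120)
  expect_equal(season_lengths(as.Date("2019-03-13"), as.Date("2019-07-10")), 120)
  # whole year
  expect_equal(season_lengths(1, 365), 365)
})

test_that("within-season meteorological correlations behave like Pearson's r", {
  seasons <- tibble::tibble(
    season = c("a", "b"), start_doy = c(1, 150), end_doy = c(149, 366)
  )
  dates <- as.Date("2019-01-01") + 0:364
  rate <- 100 + 50 * sin(2 * pi * (1:365) / 365)
  # temperature a negative affine transform of the rate: r = -1
  met <- tibble::tibble(
    date = dates, temperature = 40 - 0.1 * rate,
    humidity = rnorm(365, 50, 5)
  )
  pred <- tibble::tibble(date = dates, rate = rate)
  out <- correlate_with_met(pred, met, seasons)
  tmp <- out[out$variable == "temperature", ]
  expect_equal(tmp$r, c(-1, -1), tolerance = 1e-9)
  expect_true(all(tmp$p < 1e-10))

  # a 2-day season is undefined, not zero
  tiny <- tibble::tibble(season = "t", start_doy = 10, end_doy = 11)
  out2 <- correlate_with_met(pred, met, tiny)
  expect_true(all(is.na(out2$r)))
  expect_true(all(out2$n == 2))

  # constant met series within a season: undefined
  met_const <- met
  met_const$temperature <- 25
  out3 <- correlate_with_met(pred, met_const, seasons)
  expect_true(all(is.na(out3$r[out3$variable == "temperature"])))
})

test_that("independent white-noise meteorology rarely shows |r| > 0.3 at n = 120", {
  set.seed(4)
  hits <- replicate(400, {
    abs(cor(rnorm(120), rnorm(120)))
  })
  expect_gte(mean(hits < 0.3), 0.95)
})

test_that("global mean is the average of the model's own predictions", {
  m <- fixture_fit()
  expect_equal(global_mean(m), mean(m$fitted_raw))
  # definitionally row-order invariant; close to the mean of the data
  expect_lt(abs(global_mean(m) - mean(m$data$log_rate)), 0.05)
})

test_that("end-to-end delineation on the small cohort finds the three seasons", {
  m <- fixture_fit()
  out <- delineate_seasons(m)
  expect_s3_class(out, "oryx_seasons")
  expect_equal(nrow(out$periods), 3)
  expect_setequal(out$seasons$season, c("hot_dry", "rainy", "cool_dry"))
  # tiling
  expect_equal(sum(out$seasons$length_days), 365)
  expect_equal(sum(out$seasons$length_days_leap), 366)
  # the low-rate season is the hot, dry season by construction
  hot <- out$seasons[out$seasons$season == "hot_dry", ]
  expect_equal(hot$mean_rate, min(out$seasons$mean_rate))
  # level consistency: one sign change per boundary after clustering
  expect_equal(nrow(out$crossings) %% 2, 0)
  # boundaries near the generating transitions
  truth <- fixture_cohort()$config$true_transitions
  expect_true(all(circ_doy_dist(out$boundaries, truth) <= 15))
})
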