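test_that("empty and invalid configurations are handled", {
  cfg <- sim_config(n_individuals = 0)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$individuals), 0)
  expect_equal(nrow(pop$deployments), 0)
  expect_equal(nrow(pop$calf_records), 0)
  tracks <- simulate_tracks(cfg, pop)
  expect_equal(nrow(tracks$positions), 0)

  expect_error(sim_config(sd_noise = -1), "sd_noise")
  expect_error(sim_config(true_transitions = c(100, 90, 200)), "true_transitions")
  expect_error(sim_config(season_log_levels = c(1, 2)), "season_log_levels")
  expect_error(
    sim_config(artifact_rates = list(
      bad_dop = 2, timestamp = 0, speed_spike = 0, invalid_fix = 0
    )),
    "artifact_rates"
  )
  # non-stationary AR polynomial rejected
  expect_error(sim_config(ar_coefficients = c(1.2, 0, 0, 0, 0)), "stationary")
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_individuals = 4, n_years = 1, seed = 1L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$positions, b$positions)
  expect_identical(a$truth$daily, b$truth$daily)
  expect_identical(a$met, b$met)
  expect_identical(a$calf_records, b$calf_records)
})

test_that("simulated interbirth intervals never fall below 241 days", {
  cfg <- sim_config(n_individuals = 1000, sex_ratio = 1, seed = 9L)
  pop <- simulate_population(cfg)
  # oracle: direct scan of successive birth dates per dam
  gaps <- pop$calf_records %>%
    dplyr::arrange(dam_id, calf_birth_date) %>%
    dplyr::group_by(dam_id) %>%
    dplyr::summarise(
      min_gap = if (dplyr::n() > 1) {
        min(as.numeric(diff(calf_birth_date)))
      } else {
        Inf
      },
      .groups = "drop"
    )
  expect_true(all(gaps$min_gap >= 241))
  # and the documented upper range is respected too
  expect_true(all(gaps$min_gap[is.finite(gaps$min_gap)] <= 705))
})

test_that("latent log rate is periodic, additive in state, and symmetric in plateaus", {
  cfg <- sim_config()
  prof <- latent_profile(cfg)
  # periodic: Dec 31 meets Jan 1 (both deep inside the cool-dry plateau)
  expect_lt(abs(prof$level[366] - prof$level[1]), 0.02)

  # symmetry about a season midpoint, evaluated on the plateau
  mid <- mean(cfg$true_transitions[1:2]) # hot-dry midpoint
  expect_equal(
    latent_log_rate(mid - 10, "MALE", 5, cfg),
    latent_log_rate(mid + 10, "MALE", 5, cfg),
    tolerance = 1e-9
  )

  # state differences equal configured offset differences, any DOY and age
  d <- latent_log_rate(150, "MALE", 4, cfg) - latent_log_rate(150, "ET_NC", 4, cfg)
  expect_equal(d, cfg$state_offsets[["MALE"]] - cfg$state_offsets[["ET_NC"]])

  # equal season levels (no dip, no age effect) give a flat profile at L
  flat <- sim_config(
    season_log_levels = c(5, 5, 5),
    transition_dip = list(depth = 0, width = 10)
  )
  grid_vals <- latent_log_rate(1:366, "MALE", flat$age_center, flat)
  expect_equal(mean(grid_vals), 5, tolerance = 1e-9)
  expect_equal(max(abs(grid_vals - 5)), 0, tolerance = 1e-9)

  expect_error(latent_log_rate(400, "MALE", 5, cfg), "doy")
})

test_that("a 1-h schedule yields 12 daytime fixes and schedules align to 06:01", {
  # the 06:01-18:00 window (both endpoints closed) spans 11 h 59 min, so an
  # hourly fix grid can contain at most 12 daytime fixes
  cfg <- sim_config(
    n_individuals = 1, sex_ratio = 0, n_years = 1,
    fix_intervals = 1,
    artifact_rates = list(
      bad_dop = 0, timestamp = 0, speed_spike = 0, invalid_fix = 0
    ),
    seed = 5L
  )
  pop <- simulate_population(cfg)
  tracks <- simulate_tracks(cfg, pop)
  w <- day_window()
  lc <- oryxseasons:::local_clock(tracks$positions$timestamp, w)
  daytime <- lc$min >= w$start_min & lc$min <= w$end_min
  per_day <- table(lc$date[daytime])
  expect_true(all(per_day == 12))
  # 06:01 local is on the grid for every supported interval
  for (iv in c(1, 2, 4)) {
    expect_true(6 %in% oryxseasons:::schedule_hours(iv))
  }
})

test_that("noise-free tracks reproduce the latent rate exactly (movement-rate oracle)", {
  cfg <- sim_config(
    n_individuals = 3, sex_ratio = 0, n_years = 1,
    season_log_levels = c(5.2, 5.2, 5.2),
    transition_dip = list(depth = 0, width = 10),
    age_slope = 0, sd_individual = 0, sd_year = 0,
    ar_coefficients = rep(0, 5), sd_noise = 0,
    artifact_rates = list(
      bad_dop = 0, timestamp = 0, speed_spike = 0, invalid_fix = 0
    ),
    mortality_rate = 0, seed = 2L
  )
  coh <- simulate_cohort(cfg)
  dr <- daily_rates(coh$positions, coh$deployments)
  expect_gt(nrow(dr$rates), 100)
  rel_err <- abs(dr$rates$rate - exp(5.2)) / exp(5.2)
  expect_lt(max(rel_err), 0.005)
})

test_that("injected artifacts are recoverable from the truth ledger", {
  coh <- fixture_cohort()
  led <- coh$truth$artifacts
  expect_gt(nrow(led), 0)
  key_pos <- paste(coh$positions$individual_id, coh$positions$timestamp)
  expect_true(all(paste(led$individual_id, led$timestamp) %in% key_pos))
  # spiked positions really imply speeds far beyond the QC cap
  spikes <- led[led$type == "speed_spike", ]
  pos <- coh$positions
  for (i in seq_len(nrow(spikes))) {
    j <- which(pos$individual_id == spikes$individual_id[i] &
      pos$timestamp == spikes$timestamp[i])[1]
    dt <- as.numeric(pos$timestamp[j] - pos$timestamp[j - 1], units = "hours")
    spd <- haversine_m(
      pos$lon[j - 1], pos$lat[j - 1], pos$lon[j], pos$lat[j]
    ) / 1000 / dt
    expect_gt(spd, 18)
  }
})

test_that("simulated meteorology has the configured seasonal structure", {
  cfg <- small_cfg(seed = 3L)
  met <- simulate_met(cfg)
  expect_identical(met, simulate_met(cfg)) # determinism

  # correlation with the noiseless generating sinusoid
  doy <- date_to_doy(met$date)
  p <- cfg$met_params
  temp0 <- p$temp_mean + p$temp_amp * cos(2 * pi * (doy - p$temp_peak_doy) / 365.25)
  rh0 <- p$rh_mean + p$rh_amp * cos(2 * pi * (doy - p$rh_peak_doy) / 365.25)
  expect_gt(cor(met$temperature, temp0), 0.9)
  expect_gt(cor(met$humidity, rh0), 0.9)

  # humidity peaks in the rainy interval, temperature in the hot interval
  agg <- function(v) {
    vapply(split(v, doy), mean, numeric(1))
  }
  rainy <- cfg$true_transitions[2]:(cfg$true_transitions[3] - 1)
  hot <- cfg$true_transitions[1]:(cfg$true_transitions[2] - 1)
  expect_true(as.integer(names(which.max(agg(met$humidity)))) %in% rainy)
  expect_true(as.integer(names(which.max(agg(met$temperature)))) %in% hot)

  # zero amplitude and zero noise give a constant series
  flat <- small_cfg(met_params = list(
    temp_mean = 30, temp_amp = 0, temp_peak_doy = 135, temp_sd = 0,
    rh_mean = 40, rh_amp = 0, rh_peak_doy = 228, rh_sd = 0
  ))
  met_flat <- simulate_met(flat)
  expect_equal(var(met_flat$temperature), 0)
  expect_equal(var(met_flat$humidity), 0)
})

test_that("simulated AR(5) noise matches its theoretical autocorrelation", {
  phi <- c(0.25, 0.15, 0.10, 0.08, 0.06)
  set.seed(99)
  x <- oryxseasons:::simulate_ar_noise(10000, phi, 1)
  emp <- acf(x, lag.max = 5, plot = FALSE)$acf[2:6]
  theo <- ARMAacf(ar = phi, lag.max = 5)[2:6]
  # Monte-Carlo error at n = 10,000 for a short-memory series
  expect_true(all(abs(emp - theo) < 0.04))
})
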