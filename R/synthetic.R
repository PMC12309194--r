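# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# smooth three-phase periodic latent profile of log daytime movement rate,
# additive reproductive-state and age effects, individual and year random
# intercepts, AR(5) day-to-day noise on the log scale, mixed 1/2/4-hour fix
# schedules, and injectable QC artifacts (bad DOP, timestamp errors, speed
# spikes, invalid fixes). The generating truth is exposed alongside the
# data so recovery tests can compare against it.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a cohort resembling the reintroduced-oryx setting: 40
#' collared animals (about 64% female, mirroring a 66:38 female:male
#' cohort), tracked for two calendar years; season boundaries at DOY 55,
#' 210 and 320 (Feb 24 / Jul 29 / Nov 16, non-leap); per-season mean log
#' rates `log(93)`, `log(255)`, `log(252)` (m/h); state offsets with the
#' largest depressions for not-pregnant dams with dependent young;
#' individual-intercept SD 0.39 and year-effect SD 0.07 (log scale); AR(5)
#' coefficients (0.25, 0.15, 0.10, 0.08, 0.06) with innovation SD 0.45.
#'
#' @param n_individuals Number of collared animals.
#' @param sex_ratio Fraction female.
#' @param study_start First date of the study span (`Date`).
#' @param n_years Length of the study span in years.
#' @param true_transitions Three strictly increasing DOYs where the latent
#'   profile changes level; these are the season boundaries the pipeline
#'   should recover.
#' @param season_log_levels Mean log rate (log m/h) of the three seasons
#'   delimited by `true_transitions` (season 1 spans
#'   `[transitions[1], transitions[2] - 1]`, and so on, wrapping).
#' @param transition_width Half-width (days) of the smoothed transition
#'   between season plateaus.
#' @param transition_dip Post-rains lull: a brief Gaussian depression of
#'   the latent profile centred on the third transition (`depth` in log
#'   units, `width` = Gaussian sd in days). The rainy and cool-dry
#'   plateaus both sit above the profile's global mean, so without this
#'   transient return to the mean the rainy-to-cool-dry handover would
#'   produce no mean crossing at all (a periodic curve crosses any level
#'   an even number of times); the lull reproduces the brief transitional
#'   excursion through the global mean that the delineation method keys
#'   on. Set `depth = 0` to disable.
#' @param state_offsets Named additive log-rate offsets per reproductive
#'   state (reference `MALE = 0`).
#' @param age_slope Log-rate change per year of age.
#' @param age_center Age (years) at which the age term is zero.
#' @param sd_individual,sd_year SDs of individual and year random
#'   intercepts (log scale).
#' @param ar_coefficients AR coefficients phi_1..phi_5 of the daily
#'   log-scale noise; must define a stationary process.
#' @param sd_noise Innovation SD of the AR process.
#' @param fix_intervals Multiset of collar fix intervals in hours; each
#'   individual is assigned one, drawn uniformly. Only 1, 2 and 4 h are
#'   supported.
#' @param artifact_rates Named list of injection probabilities per
#'   position: `bad_dop`, `timestamp`, `speed_spike`, `invalid_fix`.
#' @param met_params Sinusoid parameters for daily meteorology:
#'   `temp_mean`, `temp_amp`, `temp_peak_doy`, `temp_sd`, `rh_mean`,
#'   `rh_amp`, `rh_peak_doy`, `rh_sd`.
#' @param n_release_groups Number of staged release groups (released
#'   before the study span so the 10-week post-release exclusion does not
#'   eat into it).
#' @param mortality_rate Per-individual probability of dying during the
#'   span.
#' @param calf_mortality_rate Probability a calf dies within its first 122
#'   days.
#' @param uncertain_birth_rate Probability a calf's birth date is flagged
#'   uncertain.
#' @param base_lon,base_lat Anchor coordinates of the release site
#'   (decimal degrees; default central Chad).
#' @param seed Integer RNG seed; all generator stages derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 40,
                       sex_ratio = 66 / 104,
                       study_start = as.Date("2019-01-01"),
                       n_years = 2,
                       true_transitions = c(55, 210, 320),
                       season_log_levels = log(c(93, 255, 252)),
                       transition_width = 8,
                       transition_dip = list(depth = 1.0, width = 12),
                       state_offsets = c(
                         MALE = 0,
                         ET_NC = -0.05, ET_NEO = -0.30, ET_CALF = -0.15,
                         LT_NC = -0.20,
                         NP_NC = -0.10, NP_NEO = -0.53, NP_CALF = -0.35
                       ),
                       age_slope = -0.03,
                       age_center = 5,
                       sd_individual = 0.39,
                       sd_year = 0.07,
                       ar_coefficients = c(0.25, 0.15, 0.10, 0.08, 0.06),
                       sd_noise = 0.45,
                       fix_intervals = c(1, 2, 4),
                       artifact_rates = list(
                         bad_dop = 0.01, timestamp = 0.002,
                         speed_spike = 0.002, invalid_fix = 0.002
                       ),
                       met_params = list(
                         temp_mean = 30, temp_amp = 8, temp_peak_doy = 135,
                         temp_sd = 1.5,
                         rh_mean = 35, rh_amp = 25, rh_peak_doy = 228,
                         rh_sd = 5
                       ),
                       n_release_groups = 2,
                       mortality_rate = 0.05,
                       calf_mortality_rate = 0.2,
                       uncertain_birth_rate = 0.05,
                       base_lon = 19.5, base_lat = 15.0,
                       seed = 42L) {
  cfg <- list(
    n_individuals = n_individuals, sex_ratio = sex_ratio,
    study_start = as.Date(study_start), n_years = n_years,
    true_transitions = true_transitions,
    season_log_levels = season_log_levels,
    transition_width = transition_width,
    transition_dip = transition_dip,
    state_offsets = state_offsets,
    age_slope = age_slope, age_center = age_center,
    sd_individual = sd_individual, sd_year = sd_year,
    ar_coefficients = ar_coefficients, sd_noise = sd_noise,
    fix_intervals = fix_intervals, artifact_rates = artifact_rates,
    met_params = met_params,
    n_release_groups = n_release_groups,
    mortality_rate = mortality_rate,
    calf_mortality_rate = calf_mortality_rate,
    uncertain_birth_rate = uncertain_birth_rate,
    base_lon = base_lon, base_lat = base_lat,
    seed = as.integer(seed)
  )
  cfg$study_end <- cfg$study_start + round(cfg$n_years * 365.25) - 1
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, msg) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "oryx_config_error")
  }
  if (cfg$n_individuals < 0 || cfg$n_individuals != round(cfg$n_individuals)) {
    stop_field("n_individuals", "must be a non-negative integer")
  }
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) {
    stop_field("sex_ratio", "must lie in [0, 1]")
  }
  if (length(cfg$true_transitions) != 3 ||
        any(diff(cfg$true_transitions) <= 0) ||
        any(cfg$true_transitions < 1 | cfg$true_transitions > 366)) {
    stop_field("true_transitions", "must be 3 strictly increasing DOYs in [1, 366]")
  }
  if (length(cfg$season_log_levels) != 3) {
    stop_field("season_log_levels", "must have exactly 3 entries")
  }
  if (cfg$transition_dip$depth < 0 || cfg$transition_dip$width <= 0) {
    stop_field("transition_dip", "depth must be >= 0 and width > 0")
  }
  for (f in c("sd_individual", "sd_year", "sd_noise")) {
    if (cfg[[f]] < 0) stop_field(f, "must be >= 0")
  }
  rates <- unlist(cfg$artifact_rates)
  if (any(rates < 0 | rates > 1)) {
    stop_field("artifact_rates", "probabilities must lie in [0, 1]")
  }
  if (!all(cfg$fix_intervals %in% c(1, 2, 4))) {
    stop_field("fix_intervals", "only 1, 2 and 4 hour schedules are supported")
  }
  phi <- cfg$ar_coefficients
  if (length(phi) > 0 && any(Mod(polyroot(c(1, -phi))) <= 1)) {
    stop_field("ar_coefficients", "AR polynomial must be stationary (roots outside unit circle)")
  }
  missing_states <- setdiff(setdiff(repro_state_levels(), "EXCLUDED_UNKNOWN"),
                            names(cfg$state_offsets))
  if (length(missing_states) > 0) {
    stop_field("state_offsets", paste("missing states:", paste(missing_states, collapse = ", ")))
  }
  invisible(cfg)
}

# Smooth three-phase periodic profile on the DOY grid 1..366. A piecewise-
# constant step function at the configured season levels is smoothed by two
# passes of a circular moving average of half-width `transition_width`,
# giving piecewise-smooth transitions centred on the boundaries and exact
# plateaus further than 2*width from any boundary.
#' Latent seasonal profile of the generator
#' @param cfg A [sim_config()].
#' @return Tibble with `doy` (1..366) and `level` (log m/h).
#' @export
latent_profile <- function(cfg) {
  doy <- 1:366
  b <- cfg$true_transitions
  season <- ifelse(doy >= b[1] & doy < b[2], 1L,
    ifelse(doy >= b[2] & doy < b[3], 2L, 3L)
  )
  level <- cfg$season_log_levels[season]
  w <- round(cfg$transition_width)
  if (w > 0) {
    k <- rep(1 / (2 * w + 1), 2 * w + 1)
    for (pass in 1:2) {
      level <- as.numeric(stats::filter(level, k, method = "convolution",
                                        sides = 2, circular = TRUE))
    }
  }
  dip <- cfg$transition_dip
  if (!is.null(dip) && dip$depth > 0) {
    level <- level - dip$depth *
      exp(-0.5 * (circ_dist(doy, b[3]) / dip$width)^2)
  }
  tibble(doy = doy, level = level)
}

#' Latent log movement rate of the generating model
#'
#' The generator's mean structure before noise: seasonal profile at `doy`
#' plus the configured state offset plus a linear age term centred at
#' `cfg$age_center`. Periodic in DOY (period 366, linear interpolation
#' between grid days).
#'
#' @param doy Day of year, in `[1, 366]` (fractional allowed).
#' @param state Reproductive state label (see [repro_state_levels()]);
#'   `EXCLUDED_UNKNOWN` days move like `NP_NC`.
#' @param age Age in years.
#' @param cfg A [sim_config()].
#' @return Log rate (log m/h), vectorised.
#' @export
latent_log_rate <- function(doy, state, age, cfg) {
  if (any(doy < 1 | doy > 366)) abort("`doy` must lie in [1, 366]")
  prof <- latent_profile(cfg)$level
  # periodic linear interpolation on the 366-day circle
  i0 <- floor(doy)
  frac <- doy - i0
  i1 <- ifelse(i0 >= 366, 1, i0 + 1)
  base <- prof[i0] * (1 - frac) + prof[i1] * frac
  state <- as.character(state)
  state[state == "EXCLUDED_UNKNOWN"] <- "NP_NC"
  offs <- cfg$state_offsets[state]
  if (any(is.na(offs))) abort("unknown state label in `state`")
  base + as.numeric(offs) + cfg$age_slope * (age - cfg$age_center)
}

#' Simulate the collared population and its life histories
#'
#' Draws individuals (sex, birth date, release date/group, fix interval,
#' optional mortality) and, for females, calving histories: first
#' conception at a uniform 19.1--46.7 months of age, gestation fixed at
#' 258 days, and interbirth intervals of 241 days plus an exponential
#' excess with mean 36 days (truncated at 705 days), so intervals span the
#' documented 241--705 day range with median near 277.
#'
#' @param cfg A [sim_config()].
#' @return List of tibbles: `individuals` (id, sex, birth_date),
#'   `deployments` (id, release_date, release_group, fix_interval,
#'   mortality_date) and `calf_records` (dam_id, calf_birth_date,
#'   birth_date_certain, calf_mortality_date).
#' @export
simulate_population <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  empty <- list(
    individuals = tibble(
      individual_id = character(), sex = character(),
      birth_date = as.Date(character())
    ),
    deployments = tibble(
      individual_id = character(), release_date = as.Date(character()),
      release_group = integer(), fix_interval = numeric(),
      mortality_date = as.Date(character())
    ),
    calf_records = tibble(
      dam_id = character(), calf_birth_date = as.Date(character()),
      birth_date_certain = logical(), calf_mortality_date = as.Date(character())
    )
  )
  if (n == 0) {
    return(empty)
  }
  ids <- sprintf("oryx_%03d", seq_len(n))
  n_f <- round(n * cfg$sex_ratio)
  sex <- sample(c(rep("F", n_f), rep("M", n - n_f)))
  age_at_start <- runif(n, 2.2, 7) # years
  birth_date <- cfg$study_start - round(age_at_start * 365.25)
  group <- sort(rep_len(seq_len(cfg$n_release_groups), n))
  # staged releases, all >= 10 weeks before the study span opens
  release_date <- cfg$study_start - 70 - (cfg$n_release_groups - group) * 45
  fix_interval <- sample(cfg$fix_intervals, n, replace = TRUE)
  dies <- runif(n) < cfg$mortality_rate
  mortality_date <- as.Date(rep(NA, n))
  if (any(dies)) {
    span <- as.integer(cfg$study_end - cfg$study_start)
    mortality_date[dies] <- cfg$study_start +
      round(runif(sum(dies), 0.55 * span, span))
  }

  individuals <- tibble(individual_id = ids, sex = sex, birth_date = birth_date)
  deployments <- tibble(
    individual_id = ids, release_date = release_date,
    release_group = group, fix_interval = fix_interval,
    mortality_date = mortality_date
  )

  calf_records <- purrr::map_dfr(which(sex == "F"), function(i) {
    first_conception_age_m <- runif(1, 19.1, 46.7)
    conc <- birth_date[i] + round(first_conception_age_m * 30.44)
    births <- as.Date(character())
    birth <- conc + 258
    horizon <- cfg$study_end + 258
    while (birth <= horizon) {
      births <- c(births, birth)
      interbirth <- 241 + min(rexp(1, 1 / 36), 705 - 241)
      birth <- birth + round(interbirth)
    }
    end_of_life <- if (dies[i]) mortality_date[i] else as.Date("9999-12-31")
    births <- births[births <= end_of_life]
    if (length(births) == 0) {
      return(NULL)
    }
    n_b <- length(births)
    calf_dies <- runif(n_b) < cfg$calf_mortality_rate
    mort <- as.Date(rep(NA, n_b))
    mort[calf_dies] <- births[calf_dies] + sample(0:122, sum(calf_dies), replace = TRUE)
    tibble(
      dam_id = ids[i],
      calf_birth_date = births,
      birth_date_certain = runif(n_b) >= cfg$uncertain_birth_rate,
      calf_mortality_date = mort
    )
  })
  if (nrow(calf_records) == 0) calf_records <- empty$calf_records

  list(
    individuals = individuals, deployments = deployments,
    calf_records = calf_records
  )
}

#' Simulate daily meteorology
#'
#' Daily mean daytime temperature and relative humidity over the study
#' span as noisy sinusoids of DOY; by default temperature peaks in the hot
#' season (DOY 135) and humidity in the rainy season (DOY 228).
#'
#' @param cfg A [sim_config()].
#' @return Tibble with `date`, `temperature` (deg C), `humidity` (%).
#' @export
simulate_met <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  dates <- seq(cfg$study_start, cfg$study_end, by = "day")
  doy <- date_to_doy(dates)
  p <- cfg$met_params
  temp <- p$temp_mean + p$temp_amp * cos(2 * pi * (doy - p$temp_peak_doy) / 365.25) +
    rnorm(length(dates), 0, p$temp_sd)
  rh <- p$rh_mean + p$rh_amp * cos(2 * pi * (doy - p$rh_peak_doy) / 365.25) +
    rnorm(length(dates), 0, p$rh_sd)
  tibble(date = dates, temperature = temp, humidity = pmin(pmax(rh, 0), 100))
}

# AR(p) noise series of length n (recursive filter on normal innovations,
# 200-day burn-in)
simulate_ar_noise <- function(n, phi, sd_innov) {
  if (n == 0) return(numeric(0))
  if (length(phi) == 0 || all(phi == 0) ) {
    return(rnorm(n, 0, sd_innov))
  }
  burn <- 200
  e <- rnorm(n + burn, 0, sd_innov)
  x <- as.numeric(stats::filter(e, phi, method = "recursive"))
  x[(burn + 1):(burn + n)]
}

# Per-day truth table for one cohort: latent mean, components, AR noise and
# the realised target daily rate.
simulate_truth_daily <- function(cfg, population) {
  individuals <- population$individuals
  deployments <- population$deployments
  if (nrow(individuals) == 0) {
    return(tibble(
      individual_id = character(), date = as.Date(character()),
      doy = integer(), age = numeric(),
      repro_state = factor(character(), levels = repro_state_levels()),
      ind_effect = numeric(), year_effect = numeric(),
      latent = numeric(), ar_noise = numeric(), target_rate = numeric()
    ))
  }
  ind_effect <- setNames(
    rnorm(nrow(individuals), 0, cfg$sd_individual),
    individuals$individual_id
  )
  years <- seq(
    as.integer(format(min(deployments$release_date), "%Y")),
    as.integer(format(cfg$study_end, "%Y"))
  )
  year_effect <- setNames(rnorm(length(years), 0, cfg$sd_year), as.character(years))

  days <- purrr::map_dfr(seq_len(nrow(deployments)), function(i) {
    dep <- deployments[i, ]
    to <- min(cfg$study_end, dep$mortality_date, na.rm = TRUE)
    if (to < dep$release_date) return(NULL)
    tibble(
      individual_id = dep$individual_id,
      date = seq(dep$release_date, to, by = "day")
    )
  })
  days <- assign_repro_states(days, individuals, population$calf_records)
  days <- days %>%
    left_join(individuals, by = "individual_id") %>%
    mutate(
      doy = date_to_doy(.data$date),
      age = as.numeric(.data$date - .data$birth_date) / 365.25,
      year = format(.data$date, "%Y"),
      ind_effect = unname(ind_effect[.data$individual_id]),
      year_effect = unname(year_effect[.data$year]),
      latent = latent_log_rate(.data$doy, .data$repro_state, .data$age, cfg) +
        .data$ind_effect + .data$year_effect
    )
  days <- days %>%
    group_by(.data$individual_id) %>%
    arrange(.data$date, .by_group = TRUE) %>%
    mutate(ar_noise = simulate_ar_noise(n(), cfg$ar_coefficients, cfg$sd_noise)) %>%
    ungroup() %>%
    mutate(target_rate = exp(.data$latent + .data$ar_noise)) %>%
    select(
      "individual_id", "date", "doy", "age", "repro_state",
      "ind_effect", "year_effect", "latent", "ar_noise", "target_rate"
    )
  days
}

# Fix schedule (local hours at :01 past the hour) for a fix interval. The
# grid is aligned so 06:01 is always sampled.
schedule_hours <- function(interval) {
  offset <- 6 %% interval
  seq(offset, 23, by = interval)
}

#' Simulate GPS collar tracks realising the latent movement process
#'
#' Positions are synthesised by placing successive fixes at uniformly
#' random bearings with step lengths `rate x elapsed hours`, where the
#' rate is the day's realised rate `exp(latent + AR noise)`; the analysis
#' consumes rates rather than paths, so path realism is deliberately not
#' modelled. Fixes follow each individual's schedule (hours at :01 local
#' time, grid aligned to 06:01). Artifacts are injected at the configured
#' rates and logged in a truth ledger.
#'
#' @param cfg A [sim_config()].
#' @param population Output of [simulate_population()].
#' @return List: `positions` (tibble: individual_id, timestamp UTC, lon,
#'   lat, dop, valid_fix), `truth_daily` (per individual-day latent
#'   components and target rate) and `artifacts` (ledger of injected
#'   artifacts: individual_id, timestamp, type).
#' @export
simulate_tracks <- function(cfg, population) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)
  truth_daily <- simulate_truth_daily(cfg, population)
  deployments <- population$deployments
  m_per_deg <- EARTH_RADIUS_M * pi / 180

  positions <- purrr::map_dfr(seq_len(nrow(deployments)), function(i) {
    dep <- deployments[i, ]
    truth_i <- truth_daily %>%
      filter(.data$individual_id == dep$individual_id) %>%
      arrange(.data$date)
    if (nrow(truth_i) == 0) return(NULL)
    hours <- schedule_hours(dep$fix_interval)
    n_per_day <- length(hours)
    n_days <- nrow(truth_i)
    # local fix datetimes; UTC = local - 1 h
    local <- rep(as.POSIXct(paste(truth_i$date, "00:00:00"), tz = "UTC"),
                 each = n_per_day) +
      rep(hours * 3600 + 60, times = n_days)
    ts_utc <- local - 3600
    rate <- rep(truth_i$target_rate, each = n_per_day) # keyed by local date of step start
    n_fix <- length(local)
    dt_h <- as.numeric(diff(ts_utc), units = "hours")
    step_m <- rate[-n_fix] * dt_h
    bearing <- runif(n_fix - 1, 0, 2 * pi)
    # planar small-step cumulation (checked to reproduce haversine step
    # lengths to well under 0.1%)
    start_lon <- cfg$base_lon + runif(1, -0.3, 0.3)
    start_lat <- cfg$base_lat + runif(1, -0.3, 0.3)
    dlat_deg <- step_m * cos(bearing) / m_per_deg
    lat <- start_lat + c(0, cumsum(dlat_deg))
    dlon_deg <- step_m * sin(bearing) /
      (m_per_deg * cos(lat[-n_fix] * pi / 180))
    lon <- start_lon + c(0, cumsum(dlon_deg))
    tibble(
      individual_id = dep$individual_id,
      timestamp = ts_utc,
      lon = lon, lat = lat,
      dop = runif(n_fix, 0.8, 4.5),
      valid_fix = TRUE
    )
  })

  if (nrow(positions) == 0) {
    return(list(
      positions = tibble(
        individual_id = character(),
        timestamp = as.POSIXct(character(), tz = "UTC"),
        lon = numeric(), lat = numeric(), dop = numeric(),
        valid_fix = logical()
      ),
      truth_daily = truth_daily,
      artifacts = tibble(
        individual_id = character(),
        timestamp = as.POSIXct(character(), tz = "UTC"),
        type = character()
      )
    ))
  }

  # artifact injection (never on the first fix of an individual, so every
  # artifact has a preceding position)
  positions <- positions %>%
    group_by(.data$individual_id) %>%
    mutate(.first = row_number() == 1) %>%
    ungroup()
  n_pos <- nrow(positions)
  eligible <- which(!positions$.first)
  rates <- cfg$artifact_rates
  draw <- function(rate) {
    if (rate <= 0 || length(eligible) == 0) return(integer(0))
    k <- rbinom(1, length(eligible), rate)
    if (k == 0) return(integer(0))
    picked <- sample(eligible, min(k, length(eligible)))
    # keep artifacts non-adjacent so each sits between clean fixes and every
    # injected error is individually detectable
    eligible <<- setdiff(eligible, c(picked - 1L, picked, picked + 1L))
    picked
  }
  idx_dop <- draw(rates$bad_dop %||% 0)
  idx_ts <- draw(rates$timestamp %||% 0)
  idx_spike <- draw(rates$speed_spike %||% 0)
  idx_invalid <- draw(rates$invalid_fix %||% 0)

  if (length(idx_dop) > 0) {
    positions$dop[idx_dop] <- runif(length(idx_dop), 5.0, 15)
  }
  if (length(idx_ts) > 0) {
    # duplicate the previous fix's timestamp: a non-increasing record
    positions$timestamp[idx_ts] <- positions$timestamp[idx_ts - 1L]
  }
  if (length(idx_spike) > 0) {
    # displace far enough that the implied speed from the previous fix is
    # well above 18 km/h on even a 4-h schedule
    dt_prev <- as.numeric(
      positions$timestamp[idx_spike] - positions$timestamp[idx_spike - 1L],
      units = "hours"
    )
    dt_prev[dt_prev <= 0] <- 4
    dist_km <- runif(length(idx_spike), 30, 80) * dt_prev
    dest <- destination_point(
      positions$lon[idx_spike], positions$lat[idx_spike],
      runif(length(idx_spike), 0, 2 * pi), dist_km * 1000
    )
    positions$lon[idx_spike] <- dest$lon
    positions$lat[idx_spike] <- dest$lat
  }
  if (length(idx_invalid) > 0) {
    positions$valid_fix[idx_invalid] <- FALSE
  }

  artifacts <- bind_rows(
    tibble(idx = idx_dop, type = "bad_dop"),
    tibble(idx = idx_ts, type = "timestamp"),
    tibble(idx = idx_spike, type = "speed_spike"),
    tibble(idx = idx_invalid, type = "invalid_fix")
  )
  artifacts <- tibble(
    individual_id = positions$individual_id[artifacts$idx],
    timestamp = positions$timestamp[artifacts$idx],
    type = artifacts$type
  )
  positions$.first <- NULL

  list(positions = positions, truth_daily = truth_daily, artifacts = artifacts)
}

#' Simulate a full synthetic cohort
#'
#' Runs [simulate_population()], [simulate_tracks()] and [simulate_met()]
#' and bundles their outputs with the generating truth.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `oryx_cohort`: `individuals`, `deployments`,
#'   `calf_records`, `positions`, `met`, `truth` (with `daily` and
#'   `artifacts`) and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  population <- simulate_population(cfg)
  met <- simulate_met(cfg)
  tracks <- simulate_tracks(cfg, population)
  structure(
    list(
      individuals = population$individuals,
      deployments = population$deployments,
      calf_records = population$calf_records,
      positions = tracks$positions,
      met = met,
      truth = list(daily = tracks$truth_daily, artifacts = tracks$artifacts),
      config = cfg
    ),
    class = "oryx_cohort"
  )
}
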