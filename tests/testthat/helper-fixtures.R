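# Shared fixtures, built lazily and cached for the whole test run. The
# "small" cohort (12 individuals x 2 years) keeps module tests fast; the
# full default cohort (40 x 2 years) is reserved for the acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

small_cfg <- function(seed = 42L, ...) {
  sim_config(n_individuals = 12, n_years = 2, seed = seed, ...)
}

fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(small_cfg())
  }
  .fixture_env$cohort
}

# QC'd, covariate-augmented daily rates for the small cohort
fixture_rates <- function() {
  if (is.null(.fixture_env$rates)) {
    coh <- fixture_cohort()
    qc <- qc_positions(coh$positions, coh$deployments)
    dr <- daily_rates(qc$retained, coh$deployments)
    keep <- individual_inclusion(dr$rates)
    kept_ids <- keep$individual_id[keep$keep]
    rates <- dr$rates %>%
      dplyr::filter(individual_id %in% kept_ids) %>%
      augment_rates(coh$individuals, coh$calf_records, coh$deployments)
    .fixture_env$rates <- rates
  }
  .fixture_env$rates
}

fixture_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    .fixture_env$fit <- fit_gamm(fixture_rates(), model_spec())
  }
  .fixture_env$fit
}

# full-scale default cohort pipeline run, shared by the acceptance tests
acceptance_run <- function() {
  if (is.null(.fixture_env$acc_run)) {
    .fixture_env$acc_run <- run_pipeline(
      pipeline_config(synthetic = sim_config(seed = 42L))
    )
  }
  .fixture_env$acc_run
}

# positions laid out due north from a start point with given step lengths
# (meters) and timestamps; used to build hand-checked trajectories
make_track <- function(id, t0, dt_hours, step_m,
                       lon0 = 19.5, lat0 = 15.0, dop = 2) {
  m_per_deg_lat <- 6371008.8 * pi / 180
  lat <- lat0 + cumsum(c(0, step_m)) / m_per_deg_lat
  tibble::tibble(
    individual_id = id,
    timestamp = t0 + cumsum(c(0, dt_hours)) * 3600,
    lon = lon0,
    lat = lat,
    dop = dop,
    valid_fix = TRUE
  )
}

circ_doy_dist <- function(a, b, period = 366) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}
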