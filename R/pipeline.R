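# Pipeline orchestration: raw inputs (or a synthetic cohort) -> QC ->
# daily rates -> reproductive states -> seasonal GAMM -> seasons ->
# meteorological associations, with a run manifest for provenance.

read_checked <- function(path, required, col_types) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # suppress readr's unused-parser warning; missing columns are reported
  # explicitly below
  d <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  )
  miss <- setdiff(required, names(d))
  if (length(miss) > 0) {
    abort(sprintf(
      "%s lacks required column(s): %s", basename(path),
      paste(miss, collapse = ", ")
    ))
  }
  d
}

# split a data frame into valid rows and an error report with line numbers
partition_malformed <- function(d, bad, what) {
  problems <- tibble(
    line = which(bad) + 1L, # +1 for the header line
    problem = what[bad]
  )
  list(ok = d[!bad, , drop = FALSE], problems = problems)
}

#' Read a tracking CSV
#'
#' Expects Movebank-style columns `individual_id`, `timestamp` (ISO-8601
#' UTC), `location_long`, `location_lat`, `dop` (and optionally
#' `valid_fix`). Malformed rows (unparseable timestamps, out-of-range
#' coordinates, negative DOP) are dropped and reported, with their line
#' numbers, in the `"problems"` attribute.
#'
#' @param path CSV path.
#' @return Position tibble (`individual_id`, `timestamp`, `lon`, `lat`,
#'   `dop`, `valid_fix`).
#' @export
read_tracking <- function(path) {
  d <- read_checked(
    path,
    c("individual_id", "timestamp", "location_long", "location_lat", "dop"),
    readr::cols(
      individual_id = readr::col_character(),
      timestamp = readr::col_character(),
      location_long = readr::col_double(),
      location_lat = readr::col_double(),
      dop = readr::col_double(),
      .default = readr::col_guess()
    )
  )
  # strptime returns NA on unparseable rows instead of erroring
  ts <- as.POSIXct(strptime(d$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  plain <- is.na(ts)
  if (any(plain)) {
    ts[plain] <- as.POSIXct(
      strptime(d$timestamp[plain], "%Y-%m-%d %H:%M:%S", tz = "UTC")
    )
  }
  bad_ts <- is.na(ts)
  bad_lon <- is.na(d$location_long) | abs(d$location_long) > 180
  bad_lat <- is.na(d$location_lat) | abs(d$location_lat) > 90
  bad_dop <- is.na(d$dop) | d$dop < 0
  what <- dplyr::case_when(
    bad_ts ~ "unparseable timestamp",
    bad_lon ~ "longitude out of range",
    bad_lat ~ "latitude out of range",
    bad_dop ~ "invalid dop",
    TRUE ~ NA_character_
  )
  out <- tibble(
    individual_id = d$individual_id,
    timestamp = ts,
    lon = d$location_long,
    lat = d$location_lat,
    dop = d$dop,
    valid_fix = if ("valid_fix" %in% names(d)) as.logical(d$valid_fix) else TRUE
  )
  parts <- partition_malformed(out, !is.na(what), what)
  res <- parts$ok %>% arrange(.data$individual_id, .data$timestamp)
  attr(res, "problems") <- parts$problems
  res
}

#' Write a tracking CSV
#' @param positions Position tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(positions, path) {
  out <- tibble(
    individual_id = positions$individual_id,
    timestamp = format(positions$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    location_long = positions$lon,
    location_lat = positions$lat,
    dop = positions$dop,
    valid_fix = if ("valid_fix" %in% names(positions)) positions$valid_fix else TRUE
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a deployment CSV
#'
#' Columns: `individual_id`, `release_date`, `release_group`,
#' `fix_interval`, `mortality_date` (blank when alive).
#' @param path CSV path.
#' @return Deployment tibble.
#' @export
read_deployments <- function(path) {
  read_checked(
    path,
    c("individual_id", "release_date", "release_group", "fix_interval"),
    readr::cols(
      individual_id = readr::col_character(),
      release_date = readr::col_date(),
      release_group = readr::col_integer(),
      fix_interval = readr::col_double(),
      mortality_date = readr::col_date(),
      .default = readr::col_guess()
    )
  )
}

#' Read a life-history CSV
#'
#' One file holds both record kinds: individual rows (`individual_id`,
#' `sex`, `birth_date`, calf fields blank) and calf rows (`dam_id`,
#' `calf_birth_date`, `birth_date_certain`, `calf_mortality_date`,
#' individual fields blank).
#'
#' @param path CSV path.
#' @return List with `individuals` and `calf_records` tibbles.
#' @export
read_lifehistory <- function(path) {
  d <- read_checked(
    path, character(0),
    readr::cols(
      individual_id = readr::col_character(),
      sex = readr::col_character(),
      birth_date = readr::col_date(),
      dam_id = readr::col_character(),
      calf_birth_date = readr::col_date(),
      birth_date_certain = readr::col_logical(),
      calf_mortality_date = readr::col_date(),
      .default = readr::col_guess()
    )
  )
  need <- c("individual_id", "sex", "birth_date", "dam_id", "calf_birth_date")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(sprintf("life-history file lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  list(
    individuals = d %>%
      filter(!is.na(.data$individual_id)) %>%
      select("individual_id", "sex", "birth_date"),
    calf_records = d %>%
      filter(!is.na(.data$dam_id)) %>%
      select("dam_id", "calf_birth_date", "birth_date_certain", "calf_mortality_date")
  )
}

#' Write a life-history CSV (see [read_lifehistory()] for the layout)
#' @param individuals,calf_records Tibbles as produced by
#'   [simulate_population()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lifehistory <- function(individuals, calf_records, path) {
  a <- individuals %>% mutate(
    dam_id = NA_character_, calf_birth_date = as.Date(NA),
    birth_date_certain = NA, calf_mortality_date = as.Date(NA)
  )
  b <- calf_records %>% mutate(
    individual_id = NA_character_, sex = NA_character_, birth_date = as.Date(NA)
  )
  readr::write_csv(bind_rows(a, b), path)
  invisible(path)
}

#' Read a daily meteorology CSV (`date`, `temperature`, `humidity`)
#' @param path CSV path.
#' @return Met tibble.
#' @export
read_met <- function(path) {
  read_checked(
    path,
    c("date", "temperature", "humidity"),
    readr::cols(
      date = readr::col_date(),
      temperature = readr::col_double(),
      humidity = readr::col_double(),
      .default = readr::col_guess()
    )
  )
}

#' Attach model covariates to a daily-rate table
#'
#' Joins the reproductive state (via [assign_repro_states()]), age in
#' years, release group and calendar year onto the `rates` tibble from
#' [daily_rates()], producing the row format [fit_gamm()] models.
#'
#' @param rates Rates tibble (`individual_id`, `date`, `doy`, `rate`, ...).
#' @param individuals Tibble with `individual_id`, `sex`, `birth_date`.
#' @param calf_records Calving records (see [estimate_conceptions()]).
#' @param deployments Tibble with `individual_id`, `release_group`.
#' @param constants A [repro_constants()].
#' @return The `rates` tibble with `repro_state`, `age`, `release_group`
#'   and `year` columns added.
#' @export
augment_rates <- function(rates, individuals, calf_records, deployments,
                          constants = repro_constants()) {
  rates %>%
    assign_repro_states(individuals, calf_records, constants) %>%
    left_join(individuals %>% select("individual_id", "birth_date"),
      by = "individual_id"
    ) %>%
    left_join(deployments %>% select("individual_id", "release_group"),
      by = "individual_id"
    ) %>%
    mutate(
      age = as.numeric(.data$date - .data$birth_date) / 365.25,
      year = format(.data$date, "%Y")
    ) %>%
    select(-"birth_date")
}

#' Pipeline configuration
#'
#' Either a synthetic-cohort block (`synthetic = sim_config()`) or the
#' four input paths must be supplied, not neither. All defaults echo the
#' analysis conventions: DOP cutoff 5.0, 18 km/h speed cap, 10-week
#' post-release and 2-week pre-mortality exclusions, 06:01--18:00 daytime
#' window (UTC+1), k = 10 smooths, AR order 5.
#'
#' @param synthetic A [sim_config()], or `NULL` for file input.
#' @param tracking,deployments,lifehistory,met Input CSV paths (file
#'   mode).
#' @param thresholds A [qc_thresholds()].
#' @param window A [day_window()].
#' @param constants A [repro_constants()].
#' @param spec A [model_spec()].
#' @param gap_max Transition-clustering threshold (days).
#' @param grid_step DOY grid resolution in days.
#' @param persistence Required within-season one-sidedness.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param seed Overrides the synthetic config's seed when given.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL,
                            tracking = NULL, deployments = NULL,
                            lifehistory = NULL, met = NULL,
                            thresholds = qc_thresholds(),
                            window = day_window(),
                            constants = repro_constants(),
                            spec = model_spec(),
                            gap_max = 62,
                            grid_step = 1,
                            persistence = 0.9,
                            out_dir = NULL,
                            seed = NULL) {
  paths <- list(
    tracking = tracking, deployments = deployments,
    lifehistory = lifehistory, met = met
  )
  has_paths <- !vapply(paths, is.null, logical(1))
  if (is.null(synthetic) && !all(has_paths)) {
    abort(paste(
      "configuration needs either a `synthetic` block or all four input",
      "paths (tracking, deployments, lifehistory, met)"
    ), class = "oryx_config_error")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "sim_config")) {
    abort("`synthetic` must be a sim_config()", class = "oryx_config_error")
  }
  structure(
    list(
      synthetic = synthetic, paths = paths,
      thresholds = thresholds, window = window, constants = constants,
      spec = spec, gap_max = gap_max, grid_step = grid_step,
      persistence = persistence, out_dir = out_dir, seed = seed
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "oryx_stage_error", parent = e)
  })
}

#' Run the full season-delineation pipeline
#'
#' Executes: simulate (optional) -> position QC -> daily daytime rates and
#' inclusion rules -> reproductive states -> seasonal GAMM -> season
#' delineation -> within-season meteorological correlations. Writes every
#' intermediate table plus a manifest when `out_dir` is set. The manifest
#' (configuration hash, seed, stage row counts, convergence status,
#' season count) is identical for identical configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `oryx_run`: input tables, QC log, rates and
#'   exclusions, inclusion table, model, seasons, associations, manifest
#'   (and the generating truth when synthetic).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config()")
  }

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$synthetic)) {
    cfg <- config$synthetic
    if (!is.null(config$seed)) cfg$seed <- as.integer(config$seed)
    cohort <- run_stage("simulate", simulate_cohort(cfg))
    positions <- cohort$positions
    deployments <- cohort$deployments
    individuals <- cohort$individuals
    calf_records <- cohort$calf_records
    met <- cohort$met
    truth <- cohort$truth
    seed_used <- cfg$seed
  } else {
    positions <- run_stage("read", read_tracking(config$paths$tracking))
    deployments <- run_stage("read", read_deployments(config$paths$deployments))
    lh <- run_stage("read", read_lifehistory(config$paths$lifehistory))
    individuals <- lh$individuals
    calf_records <- lh$calf_records
    met <- run_stage("read", read_met(config$paths$met))
    truth <- NULL
    seed_used <- config$seed
  }

  # --- QC -------------------------------------------------------------
  qc <- run_stage("qc", qc_positions(positions, deployments, config$thresholds))

  # --- daily rates and inclusion --------------------------------------
  dr <- run_stage("rates", daily_rates(qc$retained, deployments, config$window))
  inclusion <- run_stage("rates", individual_inclusion(dr$rates))
  kept <- inclusion$individual_id[inclusion$keep]
  rates <- dr$rates %>% filter(.data$individual_id %in% kept)
  if (nrow(rates) == 0) {
    abort("pipeline stage 'rates' failed: no individuals pass the inclusion rule",
          class = "oryx_stage_error")
  }

  # --- reproductive states and covariates -----------------------------
  rates <- run_stage(
    "states",
    augment_rates(rates, individuals, calf_records, deployments,
      constants = config$constants
    )
  )

  # --- model ----------------------------------------------------------
  model <- run_stage("fit", fit_gamm(rates, config$spec))

  # --- seasons --------------------------------------------------------
  grid <- seq(1, 366, by = config$grid_step)
  seasons <- run_stage("seasons", delineate_seasons(
    model, gap_max = config$gap_max, grid = grid,
    persistence = config$persistence
  ))

  # --- meteorology ----------------------------------------------------
  associations <- run_stage("associate", {
    pred <- predicted_daily_rates(seasons$curve, met$date)
    correlate_with_met(pred, met, seasons)
  })
  # the two non-hot seasons can sit at nearly identical movement levels;
  # humidity tells them apart
  relab <- relabel_seasons_by_met(seasons, associations)
  seasons <- relab$seasons
  associations <- relab$associations

  manifest <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = seed_used,
    n_positions_raw = nrow(positions),
    n_positions_retained = nrow(qc$retained),
    n_positions_rejected = nrow(qc$rejected),
    n_daily_rates = nrow(dr$rates),
    n_days_excluded = nrow(dr$excluded),
    n_individuals_kept = length(kept),
    n_modelled_rows = nrow(model$data),
    model_converged = model$converged,
    ar_coefficients = model$phi,
    n_transitional_periods = nrow(seasons$periods),
    n_seasons = nrow(seasons$seasons),
    boundaries = seasons$boundaries
  )

  run <- structure(
    list(
      positions = positions, deployments = deployments,
      individuals = individuals, calf_records = calf_records, met = met,
      qc = qc, rates = rates, excluded_days = dr$excluded,
      inclusion = inclusion, model = model, seasons = seasons,
      associations = associations, truth = truth, manifest = manifest
    ),
    class = "oryx_run"
  )
  if (!is.null(config$out_dir)) {
    write_run(run, config$out_dir)
  }
  run
}

#' Write pipeline outputs to a directory
#'
#' Writes the retained positions, rejection log, daily rates, season
#' table, associations, prediction curve, a JSON serialisation of the
#' fitted model (coefficients, AR terms, smoothing parameters, variance
#' components), and the run manifest.
#'
#' @param run An `oryx_run`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tracking(run$qc$retained, p("positions_retained.csv"))
  readr::write_csv(run$qc$rejected, p("rejection_log.csv"))
  readr::write_csv(run$rates, p("daily_rates.csv"))
  readr::write_csv(run$excluded_days, p("excluded_days.csv"))
  readr::write_csv(run$inclusion, p("inclusion.csv"))
  readr::write_csv(run$seasons$seasons, p("season_table.csv"))
  readr::write_csv(run$associations, p("associations.csv"))
  readr::write_csv(run$seasons$curve$population, p("prediction_curve.csv"))
  readr::write_csv(run$seasons$curve$by_state, p("prediction_curve_by_state.csv"))
  model <- run$model
  jsonlite::write_json(
    list(
      coefficients = as.list(coef(model$gam)),
      phi = model$phi,
      sigma = model$sigma,
      smoothing_parameters = as.list(model$gam$sp),
      variance_components = model$variance_components,
      converged = model$converged,
      iterations = model$iterations
    ),
    p("model.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a synthetic cohort to CSV inputs
#'
#' Materialises a simulated cohort as the four pipeline input files
#' (tracking, deployments, life history, met) plus the truth ledger as
#' JSON, so the file-based pipeline path can be exercised.
#'
#' @param cohort An `oryx_cohort` from [simulate_cohort()].
#' @param dir Output directory.
#' @return Named list of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list(
    tracking = file.path(dir, "tracking.csv"),
    deployments = file.path(dir, "deployments.csv"),
    lifehistory = file.path(dir, "lifehistory.csv"),
    met = file.path(dir, "met.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_tracking(cohort$positions, files$tracking)
  readr::write_csv(cohort$deployments, files$deployments)
  write_lifehistory(cohort$individuals, cohort$calf_records, files$lifehistory)
  readr::write_csv(cohort$met, files$met)
  jsonlite::write_json(
    list(
      daily = cohort$truth$daily %>%
        mutate(repro_state = as.character(.data$repro_state)),
      artifacts = cohort$truth$artifacts %>%
        mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
    ),
    files$truth,
    auto_unbox = TRUE, digits = NA
  )
  invisible(files)
}

#' @export
print.oryx_run <- function(x, ...) {
  m <- x$manifest
  cat("Season-delineation pipeline run\n")
  cat(sprintf(
    "  positions: %d raw -> %d retained (%d rejected)\n",
    m$n_positions_raw, m$n_positions_retained, m$n_positions_rejected
  ))
  cat(sprintf(
    "  daily rates: %d (from %d individuals passing inclusion)\n",
    m$n_daily_rates, m$n_individuals_kept
  ))
  cat(sprintf(
    "  model: %s | transitional periods: %d\n",
    if (m$model_converged) "converged" else "NOT converged",
    m$n_transitional_periods
  ))
  print(x$seasons)
  invisible(x)
}
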