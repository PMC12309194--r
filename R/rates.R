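# Movement-rate metrics: the response variable of the seasonal model is
# the mean daytime hourly movement rate, computed per individual-day from
# QC'd positions.

#' Daytime window definition
#'
#' The daytime period is 06:01--18:00 local clock time (both endpoints
#' included). Local time is UTC plus a fixed offset; the study region
#' (Chad) observes UTC+1 with no daylight saving.
#'
#' @param day_start,day_end Clock times as `"HH:MM"` strings.
#' @param tz_offset Hours added to UTC to obtain local time.
#' @return A list of class `day_window` with start/end in minutes past
#'   local midnight.
#' @export
day_window <- function(day_start = "06:01", day_end = "18:00", tz_offset = 1) {
  to_min <- function(x) {
    p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
    p[1] * 60L + p[2]
  }
  s <- to_min(day_start)
  e <- to_min(day_end)
  if (e <= s) abort("`day_end` must come after `day_start`")
  structure(
    list(start_min = s, end_min = e, tz_offset = tz_offset),
    class = "day_window"
  )
}

# local minutes past midnight and local date for UTC timestamps
local_clock <- function(timestamp, window) {
  local <- timestamp + window$tz_offset * 3600
  list(
    date = as.Date(local, tz = "UTC"),
    min = as.integer(format(local, "%H", tz = "UTC")) * 60L +
      as.integer(format(local, "%M", tz = "UTC"))
  )
}

#' Movement rate of a single step
#'
#' Great-circle distance between two positions divided by the elapsed
#' time, in m/h.
#'
#' @param p1,p2 Single-row data frames (or lists) with `lon`, `lat`,
#'   `timestamp`; `p2` must be later than `p1`.
#' @return Rate in m/h.
#' @export
step_rate <- function(p1, p2) {
  dt <- as.numeric(p2$timestamp - p1$timestamp, units = "hours")
  if (any(dt <= 0)) abort("`p2` must be strictly later than `p1`")
  haversine_m(p1$lon, p1$lat, p2$lon, p2$lat) / dt
}

# Core per-day computation given one individual-day's daytime positions
# (already restricted to the window and time-ordered). Returns a one-row
# tibble or a reason string.
day_rate_core <- function(sub, fix_interval, window) {
  n_pos <- nrow(sub)
  expected_steps <- (window$end_min - window$start_min + 1) / 60 / fix_interval
  if (n_pos < 2) {
    return("too_few_positions")
  }
  dist <- haversine_m(
    sub$lon[-n_pos], sub$lat[-n_pos], sub$lon[-1], sub$lat[-1]
  )
  dt <- as.numeric(diff(sub$timestamp), units = "hours")
  n_steps <- n_pos - 1
  if (!(n_pos >= 3 || n_steps >= 0.5 * expected_steps)) {
    return("too_few_positions")
  }
  span_h <- as.numeric(sub$timestamp[n_pos] - sub$timestamp[1], units = "hours")
  if (span_h < 6) {
    return("insufficient_span")
  }
  rate <- mean(dist / dt)
  if (!is.finite(rate)) {
    return("nonfinite_rate")
  }
  tibble(rate = rate, n_steps = n_steps, span_hours = span_h)
}

#' Mean daytime hourly movement rate for one individual-day
#'
#' Restricts `positions` to fixes whose local clock time falls inside the
#' daytime window on `date`, then averages the per-step rates
#' (distance / elapsed time over consecutive pairs). The day is excluded
#' (with a reason) unless at least three daytime positions or half the
#' expected steps are available and the positions span at least half the
#' daytime period (6 h).
#'
#' @param positions QC'd positions for one individual.
#' @param date Local calendar date (`Date`).
#' @param window A [day_window()].
#' @param fix_interval The individual's fix interval in hours.
#' @return One-row tibble (`date`, `rate`, `n_steps`, `span_hours`); an
#'   excluded day yields a zero-row tibble whose `"reason"` attribute
#'   explains the exclusion.
#' @export
daily_mean_daytime_rate <- function(positions, date,
                                    window = day_window(),
                                    fix_interval = 1) {
  lc <- local_clock(positions$timestamp, window)
  keep <- lc$date == as.Date(date) &
    lc$min >= window$start_min & lc$min <= window$end_min
  sub <- positions[keep, , drop = FALSE]
  sub <- sub[order(sub$timestamp), , drop = FALSE]
  res <- day_rate_core(sub, fix_interval, window)
  if (is.character(res)) {
    out <- tibble(
      date = as.Date(character()), rate = numeric(),
      n_steps = integer(), span_hours = numeric()
    )
    attr(out, "reason") <- res
    return(out)
  }
  dplyr::bind_cols(tibble(date = as.Date(date)), res)
}

#' Daily mean daytime movement rates for a whole data set
#'
#' Vectorised version of [daily_mean_daytime_rate()] over every
#' individual-day present in `positions`.
#'
#' @param positions QC'd position tibble (multiple individuals).
#' @param deployments Deployment tibble supplying `fix_interval` per
#'   individual.
#' @param window A [day_window()].
#' @return List with `rates` (tibble: individual_id, date, doy, rate,
#'   n_steps, span_hours) and `excluded` (tibble: individual_id, date,
#'   reason).
#' @export
daily_rates <- function(positions, deployments, window = day_window()) {
  positions <- as_tibble(positions)
  if (nrow(positions) == 0) {
    return(list(
      rates = tibble(
        individual_id = character(), date = as.Date(character()),
        doy = integer(), rate = numeric(), n_steps = integer(),
        span_hours = numeric()
      ),
      excluded = tibble(
        individual_id = character(), date = as.Date(character()),
        reason = character()
      )
    ))
  }
  lc <- local_clock(positions$timestamp, window)
  positions$.date <- lc$date
  positions$.daytime <- lc$min >= window$start_min & lc$min <= window$end_min
  fix_of <- setNames(deployments$fix_interval, deployments$individual_id)

  day_tbl <- positions %>%
    filter(.data$.daytime) %>%
    group_by(.data$individual_id, .data$.date) %>%
    arrange(.data$timestamp, .by_group = TRUE) %>%
    summarise(
      n_pos = n(),
      n_steps = n() - 1L,
      span_hours = as.numeric(last(.data$timestamp) - first(.data$timestamp),
                              units = "hours"),
      rate = mean(
        haversine_m(
          .data$lon[-n()], .data$lat[-n()],
          .data$lon[-1], .data$lat[-1]
        ) /
          as.numeric(diff(.data$timestamp), units = "hours")
      ),
      .groups = "drop"
    ) %>%
    rename(date = ".date") %>%
    mutate(
      expected_steps = (window$end_min - window$start_min + 1) / 60 /
        fix_of[.data$individual_id],
      reason = dplyr::case_when(
        n_pos < 2 ~ "too_few_positions",
        !(n_pos >= 3 | n_steps >= 0.5 * expected_steps) ~ "too_few_positions",
        span_hours < 6 ~ "insufficient_span",
        !is.finite(rate) ~ "nonfinite_rate",
        TRUE ~ NA_character_
      )
    )

  rates <- day_tbl %>%
    filter(is.na(.data$reason)) %>%
    mutate(doy = date_to_doy(.data$date)) %>%
    select("individual_id", "date", "doy", "rate", "n_steps", "span_hours")
  excluded <- day_tbl %>%
    filter(!is.na(.data$reason)) %>%
    select("individual_id", "date", "reason")
  list(rates = rates, excluded = excluded)
}

#' Individual-inclusion rule
#'
#' An individual is retained only if movement rates are available on at
#' least 50% of the days of year in each half of the calendar year
#' (DOY 1--181 and DOY 182--366, pooling DOYs across all years of data).
#'
#' @param rates The `rates` tibble from [daily_rates()].
#' @return Tibble: `individual_id`, `n_first_half`, `n_second_half`,
#'   `keep`.
#' @export
individual_inclusion <- function(rates) {
  rates %>%
    group_by(.data$individual_id) %>%
    summarise(
      n_first_half = n_distinct(.data$doy[.data$doy <= 181]),
      n_second_half = n_distinct(.data$doy[.data$doy >= 182]),
      .groups = "drop"
    ) %>%
    mutate(
      keep = .data$n_first_half >= 0.5 * 181 & .data$n_second_half >= 0.5 * 185
    )
}

#' Daily net displacement
#'
#' Straight-line (great-circle) distance between the first and last
#' retained daytime position of each individual-day.
#'
#' @inheritParams daily_rates
#' @return Tibble: `individual_id`, `date`, `doy`, `net_displacement_m`
#'   (days with fewer than two daytime positions are omitted).
#' @export
daily_net_displacement <- function(positions, window = day_window()) {
  positions <- as_tibble(positions)
  if (nrow(positions) == 0) {
    return(tibble(
      individual_id = character(), date = as.Date(character()),
      doy = integer(), net_displacement_m = numeric()
    ))
  }
  lc <- local_clock(positions$timestamp, window)
  positions$.date <- lc$date
  positions$.daytime <- lc$min >= window$start_min & lc$min <= window$end_min
  positions %>%
    filter(.data$.daytime) %>%
    group_by(.data$individual_id, .data$.date) %>%
    arrange(.data$timestamp, .by_group = TRUE) %>%
    summarise(
      n_pos = n(),
      net_displacement_m = haversine_m(
        first(.data$lon), first(.data$lat),
        last(.data$lon), last(.data$lat)
      ),
      .groups = "drop"
    ) %>%
    filter(.data$n_pos >= 2) %>%
    rename(date = ".date") %>%
    mutate(doy = date_to_doy(.data$date)) %>%
    select("individual_id", "date", "doy", "net_displacement_m")
}
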