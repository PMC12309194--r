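# Season delineation: the predicted population-level log-rate curve is
# compared with the global mean prediction; clusters of nearby crossings
# form transitional periods, and the median crossing DOY of each period is
# a season boundary.

#' Global mean predicted log movement rate
#'
#' The mean of the model's point predictions (log scale) over every
#' modelled individual-day, with random effects included at their
#' estimated values. This is the reference level whose crossings define
#' the seasonal transitions.
#'
#' @param model An `oryx_gamm` fit.
#' @return A log-rate scalar.
#' @export
global_mean <- function(model) {
  if (length(model$fitted_raw) == 0) abort("model has no fitted rows")
  mean(model$fitted_raw)
}

#' Find crossings of the prediction curve through a level
#'
#' Linear interpolation between adjacent grid points whose values sit on
#' opposite sides of `level`; the DOY circle is closed, so the edge from
#' the last grid day back to the first is also checked.
#'
#' @param curve An `oryx_curve` (its population curve is used) or a data
#'   frame with `doy` and `fit`.
#' @param level The reference level (log scale).
#' @param period Circle length (366 days).
#' @return Tibble of fractional crossing DOYs with `direction`
#'   (`"upward"`/`"downward"`); empty when the curve never crosses.
#' @export
find_crossings <- function(curve, level, period = 366) {
  pop <- if (inherits(curve, "oryx_curve")) curve$population else as_tibble(curve)
  s <- pop$fit - level
  doy <- pop$doy
  n <- length(s)
  s_next <- c(s[-1], s[1])
  doy_next <- c(doy[-1], doy[1] + period)
  cross <- s * s_next < 0
  if (!any(cross)) {
    return(tibble(doy = numeric(), direction = character()))
  }
  i <- which(cross)
  frac <- doy[i] + (0 - s[i]) / (s_next[i] - s[i]) * (doy_next[i] - doy[i])
  frac <- ((frac - 1) %% period) + 1
  tibble(
    doy = frac,
    direction = if_else(s_next[i] > s[i], "upward", "downward")
  ) %>%
    arrange(.data$doy)
}

#' Cluster crossings into transitional periods
#'
#' Single-linkage grouping of crossing DOYs on the circle: crossings
#' closer than `gap_max` days (circular distance) join the same
#' transitional period. Isolated crossings form singleton periods, and
#' clusters may span the year boundary.
#'
#' @param crossings Tibble from [find_crossings()].
#' @param gap_max Linkage threshold in days (default 62: at the k = 10
#'   resolution of the fitted curve a single transitional excursion can
#'   spread its two crossings up to about six weeks apart, while
#'   distinct seasonal excursions are months apart).
#' @param period Circle length.
#' @return Tibble: `period_id`, `start`, `end` (first/last crossing of the
#'   period along the circle), `n_crossings`, and the member crossings as
#'   a list column.
#' @export
cluster_transitions <- function(crossings, gap_max = 62, period = 366) {
  x <- sort(crossings$doy)
  n <- length(x)
  empty <- tibble(
    period_id = integer(), start = numeric(), end = numeric(),
    n_crossings = integer(), crossings = list()
  )
  if (n == 0) {
    return(empty)
  }
  if (n == 1) {
    return(tibble(
      period_id = 1L, start = x, end = x, n_crossings = 1L,
      crossings = list(x)
    ))
  }
  gap <- c(diff(x), x[1] + period - x[n]) # gap[i]: x[i] -> next, circularly
  breaks <- which(gap > gap_max)
  if (length(breaks) == 0) {
    # everything links into one period spanning the circle
    return(tibble(
      period_id = 1L, start = x[1], end = x[n], n_crossings = n,
      crossings = list(x)
    ))
  }
  # each cluster runs from just after one break to the next break,
  # walking the circle (the last cluster wraps back to the first break)
  m <- length(breaks)
  purrr::map_dfr(seq_len(m), function(k) {
    from <- breaks[k] + 1
    to <- if (k < m) breaks[k + 1] else breaks[1] + n
    idx <- ((seq(from, to) - 1) %% n) + 1
    members <- x[idx]
    tibble(
      start = members[1], end = members[length(members)],
      n_crossings = length(members), crossings = list(members)
    )
  }) %>%
    arrange(.data$start) %>%
    mutate(period_id = row_number()) %>%
    select("period_id", "start", "end", "n_crossings", "crossings")
}

# circular median of a period's member crossings (members may wrap)
period_median_doy <- function(members, period = 366) {
  if (length(members) > 1 && (max(members) - min(members)) > period / 2) {
    # wrapped period: shift the small values up before taking the median
    lo <- members < period / 2
    members[lo] <- members[lo] + period
  }
  m <- median(members)
  ((m - 1) %% period) + 1
}

round_half_up <- function(x) floor(x + 0.5)

#' Turn transitional periods into season boundaries and a season table
#'
#' The boundary of each transitional period is the median of its crossing
#' DOYs, rounded half-up to a whole DOY. Seasons run from one boundary
#' through the day before the next (wrapping the year). Each season's
#' interior -- the days between the end of its opening transitional
#' period and the start of the next one -- is checked for persistence: the
#' curve should sit on one side of the level on at least `persistence` of
#' those days, else a warning names the violating interval. With exactly three
#' seasons, the season with the lowest mean predicted rate is labelled
#' `hot_dry`, the highest `rainy`, and the remaining one `cool_dry`;
#' otherwise seasons are labelled `season_1`, `season_2`, ...
#'
#' @param periods Tibble from [cluster_transitions()] (at least 2 rows).
#' @param curve An `oryx_curve` or data frame with `doy` and `fit`.
#' @param level The global-mean level used for the crossings.
#' @param persistence Required one-sided fraction within each season.
#' @param labels Optional character vector of user season labels (in
#'   boundary order).
#' @param period Circle length.
#' @return List of class `oryx_seasons`: `boundaries` (integer DOYs),
#'   `periods`, `seasons` (the season table), `level`.
#' @export
season_boundaries <- function(periods, curve, level, persistence = 0.9,
                              labels = NULL, period = 366) {
  if (nrow(periods) < 2) {
    abort("cannot delineate seasons from fewer than 2 transitional periods")
  }
  pop <- if (inherits(curve, "oryx_curve")) curve$population else as_tibble(curve)
  medians <- vapply(
    periods$crossings, period_median_doy, numeric(1), period = period
  )
  ord <- order(medians)
  boundaries <- ((round_half_up(medians[ord]) - 1) %% period) + 1
  # transitional-period edges, in boundary order, for the persistence check
  p_start <- periods$start[ord]
  p_end <- periods$end[ord]
  k <- length(boundaries)

  in_arc <- function(from, to) {
    from <- ((from - 1) %% period) + 1
    to <- ((to - 1) %% period) + 1
    if (from <= to) pop$doy >= from & pop$doy <= to else pop$doy >= from | pop$doy <= to
  }

  seasons <- purrr::map_dfr(seq_len(k), function(i) {
    b0 <- boundaries[i]
    b1 <- boundaries[if (i == k) 1 else i + 1]
    end <- ((b1 - 2) %% period) + 1 # day before the next boundary
    in_season <- in_arc(b0, end)
    fit <- pop$fit[in_season]
    doys <- pop$doy[in_season]
    # persistence is judged on the season's interior: between the end of
    # this boundary's transitional period and the start of the next one
    # (a transitional excursion necessarily puts its flanks on the "wrong"
    # side of the level inside the adjacent seasons)
    interior <- in_arc(
      ceiling(p_end[i]) + 1,
      floor(p_start[if (i == k) 1 else i + 1]) - 1
    )
    sgn_int <- sign(pop$fit[interior] - level)
    frac_one_side <- max(mean(sgn_int >= 0), mean(sgn_int <= 0))
    if (frac_one_side < persistence) {
      warn(sprintf(
        "curve is not persistently one-sided between DOY %d and DOY %d (%.0f%%)",
        b0, end, 100 * frac_one_side
      ))
    }
    tibble(
      start_doy = b0, end_doy = end,
      length_days = season_lengths(b0, end, leap = FALSE),
      length_days_leap = season_lengths(b0, end, leap = TRUE),
      mean_log_rate = mean(fit),
      mean_rate = mean(exp(fit)),
      peak_rate = max(exp(fit)), peak_doy = doys[which.max(fit)],
      min_rate = min(exp(fit)), min_doy = doys[which.min(fit)]
    )
  })

  if (!is.null(labels)) {
    if (length(labels) != k) abort("`labels` must match the number of seasons")
    seasons$season <- labels
  } else if (k == 3) {
    lab <- rep("cool_dry", 3)
    lab[which.min(seasons$mean_rate)] <- "hot_dry"
    lab[which.max(seasons$mean_rate)] <- "rainy"
    seasons$season <- lab
  } else {
    seasons$season <- paste0("season_", seq_len(k))
  }
  seasons <- seasons %>%
    mutate(
      start_date = doy_label(.data$start_doy),
      end_date = doy_label(.data$end_doy)
    ) %>%
    select(
      "season", "start_doy", "end_doy", "start_date", "end_date",
      "length_days", "length_days_leap", "mean_log_rate", "mean_rate",
      "peak_rate", "peak_doy", "min_rate", "min_doy"
    )

  structure(
    list(
      boundaries = boundaries, periods = periods, seasons = seasons,
      level = level
    ),
    class = "oryx_seasons"
  )
}

#' Inclusive season length on the day-of-year circle
#'
#' Length in days from a start day through an end day inclusive, wrapping
#' the year boundary when needed. For example Mar 13 through Jul 10 is
#' 120 days, Jul 11 through Oct 1 is 83, and Oct 2 through Mar 12 is 162
#' (163 in a leap year).
#'
#' @param start,end Day of year (numeric), `Date`, or month-day strings
#'   such as `"Mar 13"`.
#' @param leap Compute the leap-year variant?
#' @return Length in days.
#' @export
season_lengths <- function(start, end, leap = FALSE) {
  ndays <- if (leap) 366L else 365L
  ref_year <- if (leap) "2020" else "2019"
  as_doy <- function(x) {
    if (is.numeric(x)) {
      return(as.integer(x))
    }
    if (!inherits(x, "Date")) {
      x <- as.Date(paste(x, ref_year), format = "%b %d %Y")
      if (any(is.na(x))) abort("could not parse date label(s)")
    }
    # re-anchor the month-day into the reference year so leap handling is
    # governed by `leap`, not by the year the caller happened to supply
    x <- as.Date(paste(ref_year, format(x, "%m-%d"), sep = "-"))
    as.integer(format(x, "%j"))
  }
  s <- as_doy(start)
  e <- as_doy(end)
  # DOYs above the year length (non-leap DOY 366) fold back
  s <- ((s - 1) %% ndays) + 1
  e <- ((e - 1) %% ndays) + 1
  ((e - s) %% ndays) + 1
}

#' Correlate predicted movement rates with meteorology within seasons
#'
#' Pearson correlation (two-sided t-test p-value) between the
#' population-level predicted daily rate (response scale) and daily mean
#' daytime temperature / relative humidity, within each season. Seasons
#' with fewer than 3 days of paired data, or a constant series, are
#' reported as undefined (`NA`) rather than zero.
#'
#' @param predicted Tibble with `date` and `rate` (e.g. from
#'   [predicted_daily_rates()]).
#' @param met Tibble with `date`, `temperature`, `humidity`.
#' @param seasons An `oryx_seasons` object (or its `seasons` tibble).
#' @return Tibble: `season`, `variable`, `r`, `p`, `n`.
#' @export
correlate_with_met <- function(predicted, met, seasons) {
  stbl <- if (inherits(seasons, "oryx_seasons")) seasons$seasons else as_tibble(seasons)
  dat <- dplyr::inner_join(as_tibble(predicted), as_tibble(met), by = "date") %>%
    mutate(doy = date_to_doy(.data$date))
  purrr::map_dfr(seq_len(nrow(stbl)), function(i) {
    b0 <- stbl$start_doy[i]
    e0 <- stbl$end_doy[i]
    in_season <- if (b0 <= e0) {
      dat$doy >= b0 & dat$doy <= e0
    } else {
      dat$doy >= b0 | dat$doy <= e0
    }
    sub <- dat[in_season, ]
    purrr::map_dfr(c("temperature", "humidity"), function(v) {
      ok <- is.finite(sub$rate) & is.finite(sub[[v]])
      x <- sub$rate[ok]
      y <- sub[[v]][ok]
      if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
        return(tibble(
          season = stbl$season[i], variable = v,
          r = NA_real_, p = NA_real_, n = length(x)
        ))
      }
      ct <- cor.test(x, y, method = "pearson")
      tibble(
        season = stbl$season[i], variable = v,
        r = unname(ct$estimate), p = ct$p.value, n = length(x)
      )
    })
  })
}

#' Predicted population-level daily rates for calendar dates
#'
#' Maps each date to its own-year DOY and reads the population curve
#' (response scale).
#'
#' @param curve An `oryx_curve`.
#' @param dates `Date` vector.
#' @return Tibble with `date` and `rate` (m/h).
#' @export
predicted_daily_rates <- function(curve, dates) {
  doy <- date_to_doy(dates)
  idx <- match(doy, round(curve$population$doy))
  tibble(date = as.Date(dates), rate = exp(curve$population$fit[idx]))
}

#' Relabel three delineated seasons using meteorology
#'
#' The rate profile identifies the hot, dry season unambiguously (lowest
#' mean predicted rate), but the rainy and cool dry seasons can have
#' nearly identical movement levels; their humidity signatures differ
#' sharply. Of the two non-hot seasons, the one whose predicted rates
#' correlate most positively with relative humidity is labelled `rainy`,
#' the other `cool_dry`.
#'
#' @param seasons An `oryx_seasons` with exactly three seasons.
#' @param associations Output of [correlate_with_met()] for those
#'   seasons.
#' @return List with the relabelled `seasons` and `associations`.
#' @export
relabel_seasons_by_met <- function(seasons, associations) {
  tb <- seasons$seasons
  if (nrow(tb) != 3) {
    return(list(seasons = seasons, associations = associations))
  }
  hot_old <- tb$season[which.min(tb$mean_rate)]
  others <- setdiff(tb$season, hot_old)
  hum <- associations[associations$variable == "humidity" &
    associations$season %in% others, ]
  r <- ifelse(is.na(hum$r), -Inf, hum$r)
  if (all(!is.finite(r))) {
    return(list(seasons = seasons, associations = associations))
  }
  rainy_old <- hum$season[which.max(r)]
  cool_old <- setdiff(others, rainy_old)
  map <- setNames(
    c("hot_dry", "rainy", "cool_dry"),
    c(hot_old, rainy_old, cool_old)
  )
  seasons$seasons$season <- unname(map[tb$season])
  associations$season <- unname(map[associations$season])
  list(seasons = seasons, associations = associations)
}

#' Delineate seasons from a fitted seasonal GAMM
#'
#' End-to-end wrapper: build the population prediction curve, take the
#' global mean of the model's predictions as the reference level, find
#' level crossings on the log scale, cluster them into transitional
#' periods, and convert period medians into season boundaries.
#'
#' @param model An `oryx_gamm` fit.
#' @param gap_max Crossing-cluster linkage threshold in days.
#' @param grid DOY prediction grid.
#' @param persistence Required one-sided fraction within each season.
#' @param state_weights Optional fixed state weights for the population
#'   curve (see [predict_curve()]).
#' @param labels Optional season labels.
#' @return An `oryx_seasons` object additionally carrying `curve`,
#'   `crossings` and `global_mean`.
#' @export
delineate_seasons <- function(model, gap_max = 62, grid = 1:366,
                              persistence = 0.9, state_weights = NULL,
                              labels = NULL) {
  curve <- predict_curve(model, grid = grid, state_weights = state_weights)
  level <- global_mean(model)
  crossings <- find_crossings(curve, level)
  periods <- cluster_transitions(crossings, gap_max = gap_max)
  out <- season_boundaries(periods, curve, level,
    persistence = persistence, labels = labels
  )
  out$curve <- curve
  out$crossings <- crossings
  out$global_mean <- level
  out
}

#' @export
print.oryx_seasons <- function(x, ...) {
  cat(sprintf(
    "Delineated %d seasons (global mean log rate %.3f)\n",
    nrow(x$seasons), x$level
  ))
  print(as.data.frame(x$seasons[, c(
    "season", "start_date", "end_date", "length_days", "mean_rate"
  )]), row.names = FALSE)
  invisible(x)
}
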