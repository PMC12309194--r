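# Position-level and deployment-window quality control.

#' QC thresholds for raw collar positions
#'
#' Defaults: retain fixes with dilution of precision (DOP) below 5.0,
#' remove implied speeds above 18 km/h (biologically unrealistic for
#' oryx), exclude the first 10 weeks after release (post-release
#' exploratory movement) and the last 2 weeks before a known mortality.
#'
#' @param dop_max Maximum acceptable DOP (fixes with `dop >= dop_max` are
#'   removed; set `dop_keep_below = FALSE` to invert the comparison).
#' @param speed_max Maximum plausible speed in km/h.
#' @param post_release_exclusion Weeks excluded after release.
#' @param pre_mortality_exclusion Weeks excluded before a known mortality.
#' @param dop_keep_below Direction of the DOP rule; the default retains
#'   low-DOP (high-precision) fixes, the standard GPS QC semantics.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(dop_max = 5.0,
                          speed_max = 18,
                          post_release_exclusion = 10,
                          pre_mortality_exclusion = 2,
                          dop_keep_below = TRUE) {
  vals <- c(dop_max, speed_max, post_release_exclusion, pre_mortality_exclusion)
  if (any(vals <= 0)) abort("all QC thresholds must be positive")
  structure(
    list(
      dop_max = dop_max, speed_max = speed_max,
      post_release_exclusion = post_release_exclusion,
      pre_mortality_exclusion = pre_mortality_exclusion,
      dop_keep_below = dop_keep_below
    ),
    class = "qc_thresholds"
  )
}

empty_rejection_log <- function() {
  tibble(
    individual_id = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    reason = character()
  )
}

#' Filter raw positions on fix validity, timestamps, DOP and speed
#'
#' Removes, in order: invalid fixes; duplicate or non-increasing
#' timestamps (the later record of the pair); fixes failing the DOP rule;
#' and fixes whose implied speed from the previous retained fix exceeds
#' `speed_max` (the later fix of the offending pair is removed, and the
#' rule is re-evaluated against the new previous retained fix until no
#' violation remains). Every removal is logged with exactly one reason.
#'
#' @param positions Data frame with `individual_id`, `timestamp`
#'   (POSIXct), `lon`, `lat`, `dop` and optionally `valid_fix`; must be
#'   sorted by timestamp within individual.
#' @param thresholds A [qc_thresholds()] list.
#' @return List with `retained` (tibble of kept positions) and `rejected`
#'   (tibble: individual_id, timestamp, reason in
#'   `{invalid_fix, timestamp, dop, speed}`).
#' @export
filter_positions <- function(positions, thresholds = qc_thresholds()) {
  positions <- as_tibble(positions)
  if (nrow(positions) == 0) {
    return(list(retained = positions, rejected = empty_rejection_log()))
  }
  if (any(positions$dop < 0, na.rm = TRUE)) {
    abort("negative DOP values present")
  }
  unsorted <- positions %>%
    group_by(.data$individual_id) %>%
    summarise(ok = !is.unsorted(.data$timestamp), .groups = "drop")
  if (any(!unsorted$ok)) {
    abort(sprintf(
      "positions not sorted by timestamp for individual(s): %s",
      paste(unsorted$individual_id[!unsorted$ok], collapse = ", ")
    ))
  }

  positions$.row <- seq_len(nrow(positions))
  reason <- rep(NA_character_, nrow(positions))

  # 1. invalid fixes
  if ("valid_fix" %in% names(positions)) {
    bad <- !positions$valid_fix
    reason[bad] <- "invalid_fix"
  }

  # 2. non-increasing timestamps among remaining fixes (drop the later record)
  live <- which(is.na(reason))
  ts_dup <- positions[live, ] %>%
    group_by(.data$individual_id) %>%
    mutate(.bad = .data$timestamp <= lag(.data$timestamp, default = as.POSIXct("1900-01-01", tz = "UTC"))) %>%
    ungroup()
  # a run of equal timestamps: every record after the first in the run goes;
  # cummax of retained timestamps handles longer non-increasing runs
  bad_ts <- ts_dup$.row[ts_dup$.bad]
  reason[bad_ts] <- "timestamp"
  # re-check: after removing flagged rows, a record is bad if <= the previous
  # retained timestamp (iterate to fixed point; runs are short in practice)
  repeat {
    live <- which(is.na(reason))
    chk <- positions[live, ] %>%
      group_by(.data$individual_id) %>%
      mutate(.bad = .data$timestamp <= lag(.data$timestamp, default = as.POSIXct("1900-01-01", tz = "UTC"))) %>%
      ungroup()
    newly <- chk$.row[chk$.bad]
    if (length(newly) == 0) break
    reason[newly] <- "timestamp"
  }

  # 3. DOP rule
  live <- which(is.na(reason))
  if (isTRUE(thresholds$dop_keep_below)) {
    bad_dop <- live[positions$dop[live] >= thresholds$dop_max]
  } else {
    bad_dop <- live[positions$dop[live] < thresholds$dop_max]
  }
  reason[bad_dop] <- "dop"

  # 4. speed rule, iterated to a fixed point: compare each live fix with the
  # previous live fix of the same individual; drop the later one of a
  # violating pair unless its predecessor is itself being dropped this pass
  repeat {
    live <- which(is.na(reason))
    if (length(live) < 2) break
    sub <- positions[live, ]
    spd <- sub %>%
      group_by(.data$individual_id) %>%
      mutate(
        .dist = haversine_m(lag(.data$lon), lag(.data$lat), .data$lon, .data$lat),
        .dt = as.numeric(.data$timestamp - lag(.data$timestamp), units = "hours"),
        .speed = .data$.dist / 1000 / .data$.dt,
        .viol = !is.na(.data$.speed) & .data$.speed > thresholds$speed_max,
        .drop = .data$.viol & !lag(.data$.viol, default = FALSE)
      ) %>%
      ungroup()
    newly <- spd$.row[spd$.drop]
    if (length(newly) == 0) break
    reason[newly] <- "speed"
  }

  rejected <- tibble(
    individual_id = positions$individual_id[!is.na(reason)],
    timestamp = positions$timestamp[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  retained <- positions[is.na(reason), ]
  retained$.row <- NULL
  list(retained = retained, rejected = rejected)
}

#' Apply deployment-window exclusions
#'
#' Drops positions earlier than 10 weeks (70 x 24 h) after the release
#' instant and, for individuals with a known mortality date, positions
#' later than 2 weeks before death. A position exactly at the 70-day mark
#' is kept; one exactly at `mortality - 14 days` is kept.
#'
#' @param positions Position tibble (as in [filter_positions()]).
#' @param deployments Tibble with `individual_id`, `release_date` (`Date`)
#'   and optionally `mortality_date`.
#' @param thresholds A [qc_thresholds()] list.
#' @return List with `retained` and `rejected` (reasons
#'   `{post_release, pre_mortality}`).
#' @export
apply_deployment_windows <- function(positions, deployments,
                                     thresholds = qc_thresholds()) {
  positions <- as_tibble(positions)
  if (nrow(positions) == 0) {
    return(list(retained = positions, rejected = empty_rejection_log()))
  }
  miss <- setdiff(unique(positions$individual_id), deployments$individual_id)
  if (length(miss) > 0) {
    abort(sprintf(
      "no deployment record for individual(s): %s",
      paste(miss, collapse = ", ")
    ))
  }
  dep <- deployments[match(positions$individual_id, deployments$individual_id), ]
  release_instant <- as.POSIXct(paste(dep$release_date, "00:00:00"), tz = "UTC")
  open_from <- release_instant + thresholds$post_release_exclusion * 7 * 24 * 3600
  too_early <- positions$timestamp < open_from
  too_late <- rep(FALSE, nrow(positions))
  has_mort <- !is.na(dep$mortality_date)
  if (any(has_mort)) {
    mort_instant <- as.POSIXct(
      paste(dep$mortality_date[has_mort], "00:00:00"),
      tz = "UTC"
    )
    # the exclusion is closed on the excluded side: the whole day at
    # mortality - 14 days is still retained
    closed_after <- mort_instant -
      thresholds$pre_mortality_exclusion * 7 * 24 * 3600 + 24 * 3600
    too_late[has_mort] <- positions$timestamp[has_mort] >= closed_after
  }
  reason <- rep(NA_character_, nrow(positions))
  reason[too_late] <- "pre_mortality"
  reason[too_early] <- "post_release"
  rejected <- tibble(
    individual_id = positions$individual_id[!is.na(reason)],
    timestamp = positions$timestamp[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  list(retained = positions[is.na(reason), ], rejected = rejected)
}

#' Run full position QC
#'
#' Convenience wrapper: [filter_positions()] then
#' [apply_deployment_windows()], with one combined rejection log.
#'
#' @inheritParams apply_deployment_windows
#' @return List with `retained` and `rejected`.
#' @export
qc_positions <- function(positions, deployments, thresholds = qc_thresholds()) {
  step1 <- filter_positions(positions, thresholds)
  step2 <- apply_deployment_windows(step1$retained, deployments, thresholds)
  list(
    retained = step2$retained,
    rejected = bind_rows(step1$rejected, step2$rejected)
  )
}
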