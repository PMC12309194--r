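# Reproductive-state labelling.
#
# A female's state on a day is the cross of her pregnancy state (early term,
# late term, not pregnant, unknown) and calf state (neonate at heel, calf at
# heel, no calf). Seven female states are reachable; late term never
# co-occurs with a dependent calf because a new conception is never placed
# earlier than the day after the previous birth, so late term (>= 130 days
# post-conception) always begins after the previous calf has passed the
# 122-day dependence cutoff.

#' Female reproductive-state levels
#'
#' The seven emittable female states, plus `MALE` and the
#' `EXCLUDED_UNKNOWN` sentinel for days whose pregnancy state cannot be
#' established (such days are dropped before modelling).
#' @export
repro_state_levels <- function() {
  c(
    "MALE",
    "ET_NC", "ET_NEO", "ET_CALF",
    "LT_NC",
    "NP_NC", "NP_NEO", "NP_CALF",
    "EXCLUDED_UNKNOWN"
  )
}

#' Reproductive timing constants
#'
#' Day-count constants for the oryx reproductive calendar: gestation lasts
#' 258 days; early term runs from conception through 129 days
#' post-conception and late term from day 130 through the day before birth;
#' any day 258 or more days after a known birth (with no subsequent known
#' conception) has unknown pregnancy state; a calf is a "neonate at heel"
#' through 30 days post-birth and a "calf at heel" from day 31 through 122
#' (about four months, the typical weaning age).
#'
#' @param gestation,early_term_max,late_term_min,unknown_after_birth,neonate_max,calf_max
#'   Day counts; see description for defaults.
#' @return A list of class `repro_constants`.
#' @export
repro_constants <- function(gestation = 258L,
                            early_term_max = 129L,
                            late_term_min = 130L,
                            unknown_after_birth = 258L,
                            neonate_max = 30L,
                            calf_max = 122L) {
  if (late_term_min != early_term_max + 1L) {
    abort("`late_term_min` must equal `early_term_max` + 1")
  }
  if (!(neonate_max < calf_max && calf_max < late_term_min + 1L)) {
    abort("require neonate_max < calf_max < late_term_min + 1")
  }
  structure(
    list(
      gestation = as.integer(gestation),
      early_term_max = as.integer(early_term_max),
      late_term_min = as.integer(late_term_min),
      unknown_after_birth = as.integer(unknown_after_birth),
      neonate_max = as.integer(neonate_max),
      calf_max = as.integer(calf_max)
    ),
    class = "repro_constants"
  )
}

#' Estimate conception dates from calf birth records
#'
#' Conception is back-dated 258 days (one gestation) from each certain calf
#' birth. Where that naive date does not fall after the previous calf's
#' birth, it is moved to the day after the previous birth (post-partum
#' conceptions are common, and a conception cannot precede the prior
#' birth). Births flagged uncertain yield no conception estimate; their
#' influence is handled by exclusion in [pregnancy_state()].
#'
#' @param calf_records Data frame with columns `dam_id`, `calf_birth_date`
#'   (`Date`), `birth_date_certain` (logical), and optionally
#'   `calf_mortality_date`.
#' @param constants A [repro_constants()] list.
#' @return A tibble with one row per certain calf: `dam_id`,
#'   `calf_birth_date`, `conception_date`, and `adjusted` (was the naive
#'   back-dated conception clamped to the previous birth + 1 day?).
#' @export
estimate_conceptions <- function(calf_records, constants = repro_constants()) {
  if (nrow(calf_records) == 0) {
    return(tibble(
      dam_id = character(), calf_birth_date = as.Date(character()),
      conception_date = as.Date(character()), adjusted = logical()
    ))
  }
  dup <- calf_records %>%
    count(.data$dam_id, .data$calf_birth_date) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate calf birth dates for dam(s): %s",
      paste(unique(dup$dam_id), collapse = ", ")
    ))
  }
  calf_records %>%
    filter(.data$birth_date_certain) %>%
    arrange(.data$dam_id, .data$calf_birth_date) %>%
    group_by(.data$dam_id) %>%
    mutate(
      naive = .data$calf_birth_date - constants$gestation,
      prev_birth = lag(.data$calf_birth_date),
      adjusted = !is.na(.data$prev_birth) & .data$naive <= .data$prev_birth,
      conception_date = if_else(.data$adjusted, .data$prev_birth + 1L, .data$naive)
    ) %>%
    ungroup() %>%
    select("dam_id", "calf_birth_date", "conception_date", "adjusted")
}

# internal: pregnancy state for one dam over a vector of dates
pregnancy_state_dam <- function(dates, conceptions, records, constants) {
  out <- rep("not_pregnant", length(dates))
  certain <- records[records$birth_date_certain, , drop = FALSE]

  # unknown overlay 1: any day >= 258 after a known birth, up to (but not
  # including) the next known conception
  if (nrow(certain) > 0) {
    births <- sort(certain$calf_birth_date)
    for (b in seq_along(births)) {
      from <- births[b] + constants$unknown_after_birth
      later_conc <- conceptions$conception_date[conceptions$conception_date > births[b]]
      to <- if (length(later_conc) > 0) min(later_conc) - 1L else as.Date("9999-12-31")
      out[dates >= from & dates <= to] <- "unknown"
    }
  }

  # unknown overlay 2: uncertain birth details blank out the window a
  # pregnancy or dependent calf tied to that birth could occupy
  uncertain <- records[!records$birth_date_certain, , drop = FALSE]
  if (nrow(uncertain) > 0) {
    for (b in seq_len(nrow(uncertain))) {
      ub <- uncertain$calf_birth_date[b]
      out[dates >= ub - constants$gestation &
            dates <= ub + constants$unknown_after_birth - 1L] <- "unknown"
    }
  }

  # known pregnancy windows take precedence
  if (nrow(conceptions) > 0) {
    for (k in seq_len(nrow(conceptions))) {
      conc <- conceptions$conception_date[k]
      birth <- conceptions$calf_birth_date[k]
      off <- as.integer(dates - conc)
      early <- off >= 0L & off <= constants$early_term_max
      late <- off >= constants$late_term_min & dates <= birth - 1L
      out[early] <- "early"
      out[late] <- "late"
    }
  }
  out
}

#' Pregnancy state of a dam on given dates
#'
#' Early term covers conception through 129 days post-conception; late term
#' covers day 130 through the day before birth. Days at least 258 days
#' after a known birth with no subsequent known conception, or days whose
#' state depends on an uncertain birth record, are `unknown` (and excluded
#' from modelling downstream). All other days are `not_pregnant`.
#'
#' @param dam_id A single dam identifier (must be female).
#' @param dates `Date` vector.
#' @param calf_records Birth records as in [estimate_conceptions()].
#' @param individuals Optional individuals table with `individual_id` and
#'   `sex`; when supplied, a male id is an error.
#' @param constants A [repro_constants()] list.
#' @return Character vector in
#'   `{"early", "late", "not_pregnant", "unknown"}`.
#' @export
pregnancy_state <- function(dam_id, dates, calf_records,
                            individuals = NULL,
                            constants = repro_constants()) {
  if (!is.null(individuals)) {
    sex <- individuals$sex[match(dam_id, individuals$individual_id)]
    if (identical(tolower(sex), "m") || identical(tolower(sex), "male")) {
      abort(sprintf("individual '%s' is male; pregnancy state is undefined", dam_id))
    }
  }
  records <- calf_records[calf_records$dam_id == dam_id, , drop = FALSE]
  conceptions <- estimate_conceptions(records, constants)
  pregnancy_state_dam(as.Date(dates), conceptions, records, constants)
}

# internal: calf state for one dam over a vector of dates
calf_state_dam <- function(dates, records, constants) {
  out <- rep("none", length(dates))
  certain <- records[records$birth_date_certain, , drop = FALSE]
  if (nrow(certain) == 0) {
    return(out)
  }
  for (k in seq_len(nrow(certain))) {
    birth <- certain$calf_birth_date[k]
    mort <- certain$calf_mortality_date[k]
    off <- as.integer(dates - birth)
    alive <- if (is.na(mort)) rep(TRUE, length(dates)) else dates <= mort
    out[off >= 0L & off <= constants$neonate_max & alive] <- "neonate"
    out[off >= constants$neonate_max + 1L & off <= constants$calf_max & alive] <- "calf"
  }
  out
}

#' Calf state of a dam on given dates
#'
#' `neonate` for a living calf 0--30 days old, `calf` for a living calf
#' 31--122 days old, `none` otherwise (including the days after a calf's
#' death).
#'
#' @inheritParams pregnancy_state
#' @return Character vector in `{"neonate", "calf", "none"}`.
#' @export
calf_state <- function(dam_id, dates, calf_records,
                       constants = repro_constants()) {
  records <- calf_records[calf_records$dam_id == dam_id, , drop = FALSE]
  calf_state_dam(as.Date(dates), records, constants)
}

combine_states <- function(preg, calf) {
  out <- character(length(preg))
  out[preg == "unknown"] <- "EXCLUDED_UNKNOWN"
  et <- preg == "early"
  out[et & calf == "none"] <- "ET_NC"
  out[et & calf == "neonate"] <- "ET_NEO"
  out[et & calf == "calf"] <- "ET_CALF"
  lt <- preg == "late"
  out[lt & calf == "none"] <- "LT_NC"
  # structurally unreachable (conception >= previous birth + 1 day implies
  # late term starts after calf dependence ends); guard against corrupt data
  if (any(lt & calf != "none")) {
    warn("late-term days with a dependent calf encountered; excluding them")
    out[lt & calf != "none"] <- "EXCLUDED_UNKNOWN"
  }
  np <- preg == "not_pregnant"
  out[np & calf == "none"] <- "NP_NC"
  out[np & calf == "neonate"] <- "NP_NEO"
  out[np & calf == "calf"] <- "NP_CALF"
  out
}

#' Reproductive state for individual-days
#'
#' Males map to `MALE`; each female-day maps to the cross of its pregnancy
#' and calf states. Days with unknown pregnancy state map to
#' `EXCLUDED_UNKNOWN`, the sentinel dropped before modelling.
#'
#' @param days Data frame with columns `individual_id` and `date`.
#' @param individuals Table with `individual_id` and `sex`
#'   (`"F"`/`"M"`, case-insensitive; `"female"`/`"male"` accepted).
#' @param calf_records Birth records as in [estimate_conceptions()].
#' @param constants A [repro_constants()] list.
#' @return The `days` tibble with a `repro_state` factor column (levels
#'   [repro_state_levels()]).
#' @export
assign_repro_states <- function(days, individuals, calf_records,
                                constants = repro_constants()) {
  days <- as_tibble(days)
  sex_of <- setNames(tolower(substr(individuals$sex, 1, 1)), individuals$individual_id)
  miss <- setdiff(unique(days$individual_id), names(sex_of))
  if (length(miss) > 0) {
    abort(sprintf("no sex recorded for individual(s): %s", paste(miss, collapse = ", ")))
  }
  days$repro_state <- NA_character_
  is_male <- sex_of[days$individual_id] == "m"
  days$repro_state[is_male] <- "MALE"

  dams <- unique(days$individual_id[!is_male])
  for (dam in dams) {
    idx <- which(days$individual_id == dam)
    dates <- as.Date(days$date[idx])
    records <- calf_records[calf_records$dam_id == dam, , drop = FALSE]
    conceptions <- estimate_conceptions(records, constants)
    preg <- pregnancy_state_dam(dates, conceptions, records, constants)
    calf <- calf_state_dam(dates, records, constants)
    days$repro_state[idx] <- combine_states(preg, calf)
  }
  days$repro_state <- factor(days$repro_state, levels = repro_state_levels())
  days
}
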