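rec <- function(dam, births, certain = TRUE, mort = as.Date(NA)) {
  tibble::tibble(
    dam_id = dam,
    calf_birth_date = as.Date(births),
    birth_date_certain = rep_len(certain, length(births)),
    calf_mortality_date = rep_len(mort, length(births))
  )
}

test_that("conception dates are birth minus one 258-day gestation", {
  out <- estimate_conceptions(rec("d1", "2020-09-15"))
  expect_equal(out$conception_date, as.Date("2020-09-15") - 258)
  expect_equal(out$conception_date, as.Date("2020-01-01")) # leap year covered
  expect_false(out$adjusted)

  # naive conception before the previous birth is clamped to birth + 1 day
  out2 <- estimate_conceptions(rec("d1", c("2020-06-01", "2021-01-15")))
  expect_equal(as.Date("2021-01-15") - 258, as.Date("2020-05-02"))
  expect_equal(out2$conception_date[2], as.Date("2020-06-02"))
  expect_true(out2$adjusted[2])

  expect_equal(nrow(estimate_conceptions(rec("d1", character(0)))), 0)
  expect_error(
    estimate_conceptions(rec("d1", c("2020-06-01", "2020-06-01"))),
    "duplicate"
  )
  # uncertain births yield no conception estimate
  expect_equal(nrow(estimate_conceptions(rec("d1", "2020-06-01", certain = FALSE))), 0)
})

test_that("pregnancy state switches early->late exactly at 129/130 days", {
  records <- rec("d1", "2020-09-15")
  conc <- as.Date("2020-01-01")
  states <- pregnancy_state("d1", conc + c(0, 129, 130, 257), records)
  expect_equal(states, c("early", "early", "late", "late"))
  # the day of birth itself is no longer "late" (late runs through birth - 1)
  expect_equal(pregnancy_state("d1", as.Date("2020-09-15"), records), "not_pregnant")

  # >= 258 days after a known birth with no subsequent conception: unknown
  birth <- as.Date("2020-09-15")
  expect_equal(pregnancy_state("d1", birth + 257, records), "not_pregnant")
  expect_equal(pregnancy_state("d1", birth + 258, records), "unknown")

  # nulliparous female before first conception
  expect_equal(pregnancy_state("d1", conc - 1, records), "not_pregnant")

  # male id is an error
  indiv <- tibble::tibble(individual_id = "m1", sex = "M")
  expect_error(pregnancy_state("m1", conc, records, individuals = indiv), "male")

  # uncertain birth details blank out the affected window
  unc <- rec("d2", "2020-09-15", certain = FALSE)
  expect_equal(pregnancy_state("d2", as.Date("2020-06-01"), unc), "unknown")
})

test_that("calf state covers neonate (<=30 d), calf (31-122 d), none", {
  birth <- as.Date("2021-03-10")
  records <- rec("d1", birth)
  states <- calf_state("d1", birth + c(0, 20, 30, 31, 60, 122, 123, 130), records)
  expect_equal(states, c(
    "neonate", "neonate", "neonate",
    "calf", "calf", "calf", "none", "none"
  ))
  # calf mortality ends the state the day after death
  records_m <- rec("d1", birth, mort = birth + 15)
  expect_equal(calf_state("d1", birth + 15, records_m), "neonate")
  expect_equal(calf_state("d1", birth + 16, records_m), "none")
})

test_that("female states combine pregnancy x calf; males are MALE", {
  indiv <- tibble::tibble(
    individual_id = c("m1", "d1"), sex = c("M", "F"),
    birth_date = as.Date("2015-01-01")
  )
  birth1 <- as.Date("2021-03-10")
  records <- rec("d1", c(birth1, birth1 + 300))
  # early term (of calf 2, conceived birth1 + 42) with calf 1 at heel
  day <- birth1 + 60
  days <- tibble::tibble(individual_id = c("m1", "d1"), date = day)
  out <- assign_repro_states(days, indiv, records)
  expect_equal(as.character(out$repro_state), c("MALE", "ET_CALF"))

  # early + neonate
  day2 <- birth1 + 25 # conception of calf 2 at birth1+42 not yet reached
  out2 <- assign_repro_states(
    tibble::tibble(individual_id = "d1", date = day2), indiv, records
  )
  expect_equal(as.character(out2$repro_state), "NP_NEO")
})

test_that("a dam's full reproductive cycle emits only the 7 female states (brute-force oracle)", {
  # two certain births 300 days apart, then nothing: sweep every day
  birth1 <- as.Date("2020-03-01")
  birth2 <- birth1 + 300
  records <- rec("dX", c(birth1, birth2))
  indiv <- tibble::tibble(individual_id = "dX", sex = "F", birth_date = as.Date("2015-06-01"))
  dates <- seq(birth1 - 600, birth2 + 600, by = "day")
  out <- assign_repro_states(
    tibble::tibble(individual_id = "dX", date = dates), indiv, records
  )

  # independent day-by-day oracle, written directly from the state rules
  conc1 <- birth1 - 258
  conc2 <- max(birth2 - 258, birth1 + 1)
  oracle <- vapply(seq_along(dates), function(i) {
    d <- dates[i]
    preg <- "not_pregnant"
    if (d >= conc1 && d <= conc1 + 129) preg <- "early"
    if (d >= conc1 + 130 && d <= birth1 - 1) preg <- "late"
    if (d >= conc2 && d <= conc2 + 129) preg <- "early"
    if (d >= conc2 + 130 && d <= birth2 - 1) preg <- "late"
    if (d >= birth2 + 258) preg <- "unknown"
    calf <- "none"
    for (b in c(birth1, birth2)) {
      if (d >= b && d <= b + 30) calf <- "neonate"
      if (d >= b + 31 && d <= b + 122) calf <- "calf"
    }
    if (preg == "unknown") {
      return("EXCLUDED_UNKNOWN")
    }
    code <- c(early = "ET", late = "LT", not_pregnant = "NP")[[preg]]
    suffix <- c(none = "NC", neonate = "NEO", calf = "CALF")[[calf]]
    paste(code, suffix, sep = "_")
  }, character(1))

  expect_equal(as.character(out$repro_state), oracle)
  emitted <- setdiff(unique(oracle), "EXCLUDED_UNKNOWN")
  expect_true(all(emitted %in% setdiff(repro_state_levels(), c("MALE", "EXCLUDED_UNKNOWN"))))
  # structural impossibility: late term never co-occurs with a dependent calf
  expect_false(any(oracle %in% c("LT_NEO", "LT_CALF")))
  expect_false(any(is.na(out$repro_state)))
})

test_that("the generator's cohorts reach all 7 female states and never LT x calf", {
  coh <- fixture_cohort()
  states <- as.character(coh$truth$daily$repro_state)
  females <- coh$individuals$individual_id[coh$individuals$sex == "F"]
  female_states <- states[coh$truth$daily$individual_id %in% females]
  expect_true(all(setdiff(
    repro_state_levels(), c("MALE", "EXCLUDED_UNKNOWN")
  ) %in% female_states))
  expect_false(any(c("LT_NEO", "LT_CALF") %in% female_states))
})

test_that("day-count arithmetic crosses leap days without drift", {
  # conception spanning Feb 29, 2020
  out <- estimate_conceptions(rec("d1", "2020-10-20"))
  expect_equal(as.numeric(as.Date("2020-10-20") - out$conception_date), 258)
  st <- pregnancy_state("d1", out$conception_date + 129:130, rec("d1", "2020-10-20"))
  expect_equal(st, c("early", "late"))
})
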