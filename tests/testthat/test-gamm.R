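test_that("cyclic cubic basis is periodic with a constant-only penalty null space", {
  x <- seq(0, 1, length.out = 200)
  b <- cyclic_cubic_basis(x, k = 10, knots = c(0, 1))
  # identical basis rows at the two ends of the period
  expect_equal(b$X[1, ], b$X[200, ], tolerance = 1e-10)
  expect_equal(
    basis_eval(b, 0)[1, ], basis_eval(b, 1)[1, ],
    tolerance = 1e-10
  )
  # the constant function (equal coefficients) incurs zero penalty
  const <- rep(1, ncol(b$X))
  expect_equal(as.numeric(t(const) %*% b$S %*% const), 0, tolerance = 1e-10)
  expect_true(isSymmetric(b$S, tol = 1e-10))
  expect_true(all(eigen(b$S, only.values = TRUE)$values > -1e-8))
  expect_error(cyclic_cubic_basis(x, k = 3), "at least 4")
})

test_that("a penalized cyclic fit recovers a known sine curve", {
  set.seed(7)
  n <- 2000
  doy <- runif(n, 1, 367)
  truth <- function(d) sin(2 * pi * d / 366)
  y <- truth(doy) + rnorm(n, 0, 0.01)
  fit <- mgcv::gam(
    y ~ s(doy, bs = "cc", k = 10),
    knots = list(doy = c(1, 367)), method = "REML"
  )
  grid <- seq(1, 366, by = 1)
  pred <- predict(fit, newdata = data.frame(doy = grid))
  expect_lt(max(abs(pred - truth(grid))), 0.05)
})

test_that("thin plate basis has an affine null space and recovers a quadratic", {
  set.seed(8)
  x <- seq(-2, 2, length.out = 300)
  b <- thin_plate_basis(x, k = 10)
  # coefficients reproducing the linear function incur zero penalty
  a_lin <- qr.solve(b$X, x)
  expect_lt(max(abs(b$X %*% a_lin - x)), 1e-8) # representable exactly
  expect_equal(as.numeric(t(a_lin) %*% b$S %*% a_lin), 0, tolerance = 1e-8)
  a_const <- qr.solve(b$X, rep(1, length(x)))
  expect_equal(as.numeric(t(a_const) %*% b$S %*% a_const), 0, tolerance = 1e-8)

  y <- x^2 + rnorm(length(x), 0, 0.01)
  fit <- mgcv::gam(y ~ s(x, bs = "tp", k = 10), method = "REML")
  expect_lt(max(abs(predict(fit) - x^2)), 0.05)

  expect_error(thin_plate_basis(rep(1:5, 10), k = 10), "distinct")
})

test_that("design columns follow the accounting identity and smooths centre", {
  m <- fixture_fit()
  d <- m$data
  S <- nlevels(d$repro_state)
  G <- nlevels(d$release_group)
  expected <- 1 + (S - 1) + (G - 1) +
    S * (m$spec$k_doy - 2) + # cyclic 'by' smooths: k-2 after centring
    S * (m$spec$k_age - 1) + # thin plate 'by' smooths: k-1 after centring
    nlevels(d$individual_id) + nlevels(d$year_f)
  expect_equal(length(coef(m$gam)), expected)

  # centering: each smooth's fitted contribution averages to ~0 over the
  # data (the identifiability constraint is applied against the full
  # covariate column, so per-level sums are approximately, not exactly, 0)
  terms <- predict(m$gam, newdata = d, type = "terms")
  sm_cols <- grep("^s\\(doy_s|^s\\(age_s", colnames(terms), value = TRUE)
  for (cl in sm_cols) {
    expect_lt(abs(sum(terms[, cl])) / nrow(d), 0.06)
  }
})

test_that("build_design validates input and degrades single-level terms", {
  expect_error(build_design(tibble::tibble(rate = 1)), "lacks column")
  r <- fixture_rates()
  # excluded-unknown rows are dropped with a logged reason
  des <- build_design(r, model_spec())
  expect_true(all(des$dropped$reason %in%
    c("unknown_repro_state", "nonpositive_rate", "missing_covariate")))
  expect_equal(nrow(des$data) + nrow(des$dropped), nrow(r))
  # single state reduces 'by' smooths to plain smooths, drops the factor
  r1 <- r[r$repro_state == "MALE", ]
  des1 <- build_design(r1, model_spec())
  expect_false(grepl("by = repro_state", deparse1(des1$formula)))
  expect_false(grepl("~repro_state \\+", deparse1(des1$formula)))
})

test_that("a constant response is fit exactly by the intercept", {
  set.seed(3)
  n_day <- 420
  r <- tibble::tibble(
    individual_id = "solo",
    date = as.Date("2019-01-01") + 0:(n_day - 1),
    doy = date_to_doy(date),
    rate = 150,
    age = 4 + (0:(n_day - 1)) / 365.25,
    repro_state = "MALE",
    release_group = 1L,
    year = format(date, "%Y")
  )
  m <- fit_gamm(r, model_spec(ar_order = 0, re_year = FALSE))
  expect_equal(unname(coef(m$gam)[1]), log(150), tolerance = 1e-6)
  expect_lt(sd(m$fitted_raw), 1e-6)
  expect_lt(m$sigma, 1e-3)
})

test_that("white-noise data yield AR coefficients near zero", {
  # a correctly specified mean model (flat profile, no lull, no age trend),
  # so raw residuals carry no structure for the AR step to absorb
  cfg <- sim_config(
    n_individuals = 28, sex_ratio = 0, n_years = 2,
    season_log_levels = c(5.2, 5.2, 5.2),
    transition_dip = list(depth = 0, width = 10),
    age_slope = 0,
    ar_coefficients = rep(0, 5), sd_noise = 0.4,
    artifact_rates = list(
      bad_dop = 0, timestamp = 0, speed_spike = 0, invalid_fix = 0
    ),
    mortality_rate = 0, seed = 21L
  )
  coh <- simulate_cohort(cfg)
  dr <- daily_rates(coh$positions, coh$deployments)
  rates <- augment_rates(
    dr$rates, coh$individuals, coh$calf_records, coh$deployments
  )
  m <- fit_gamm(rates, model_spec(include_age_smooth = FALSE))
  expect_true(m$converged)
  expect_lt(max(abs(m$phi)), 0.05)
})

test_that("the fit recovers the generating AR process and whitens residuals", {
  m <- fixture_fit()
  cfg <- fixture_cohort()$config
  expect_true(m$converged)
  # AR coefficients close to the generating (0.25, 0.15, 0.10, 0.08, 0.06)
  expect_lt(max(abs(m$phi - cfg$ar_coefficients)), 0.08)

  # whitening effectiveness: per-individual mean |acf| at lags 1-5
  d <- m$data
  rw <- m$residuals_white
  accs <- vapply(split(seq_len(nrow(d)), d$individual_id), function(idx) {
    if (length(idx) < 100) {
      return(NA_real_)
    }
    mean(abs(acf(rw[idx], lag.max = 5, plot = FALSE)$acf[2:6]))
  }, numeric(1))
  expect_lt(mean(accs, na.rm = TRUE), 2 / sqrt(mean(table(d$individual_id))))
})

test_that("select_ar_order finds the last significant PACF lag", {
  # max_lag = 6 keeps the family of per-lag 5% tests small enough that the
  # median over 21 individuals is stable
  set.seed(12)
  wn <- tibble::tibble(
    individual_id = rep(sprintf("i%02d", 1:21), each = 500),
    resid = rnorm(21 * 500)
  )
  expect_equal(as.numeric(select_ar_order(wn, max_lag = 6)), 0)

  ar1 <- tibble::tibble(
    individual_id = rep(sprintf("i%02d", 1:21), each = 1000),
    resid = as.numeric(replicate(21, arima.sim(list(ar = 0.5), 1000)))
  )
  expect_equal(as.numeric(select_ar_order(ar1, max_lag = 6)), 1)

  # individuals below the length floor are skipped with a warning
  short <- tibble::tibble(individual_id = "x", resid = rnorm(10))
  expect_warning(select_ar_order(dplyr::bind_rows(ar1, short)), "skipped")
})

test_that("prediction curves are periodic and collapse correctly for one state", {
  m <- fixture_fit()
  crv <- predict_curve(m, grid = c(1, 367))
  expect_equal(crv$population$fit[1], crv$population$fit[2], tolerance = 1e-10)

  crv_full <- predict_curve(m)
  expect_equal(nrow(crv_full$population), 366)
  expect_true(all(crv_full$population$lo <= crv_full$population$fit))
  expect_true(all(crv_full$population$hi >= crv_full$population$fit))
  expect_true(all(abs(rowSums(crv_full$weights) - 1) < 1e-9))

  # fixed equal-weight population curve stays between state extremes
  states <- levels(m$data$repro_state)
  w <- setNames(rep(1, length(states)), states)
  crv_w <- predict_curve(m, state_weights = w)
  rng <- range(crv_w$by_state$fit)
  expect_true(all(crv_w$population$fit >= rng[1] & crv_w$population$fit <= rng[2]))
  expect_error(predict_curve(m, state_weights = c(MALE = 1)), "cover")
})

test_that("population curve tracks the generating seasonal profile", {
  m <- fixture_fit()
  coh <- fixture_cohort()
  cfg <- coh$config
  crv <- predict_curve(m)
  # truth analogue: state-frequency-weighted latent curve at the same ages
  truth_daily <- coh$truth$daily
  w <- crv$weights
  states <- colnames(w)
  mean_age <- vapply(states, function(s) {
    mean(truth_daily$age[truth_daily$repro_state == s])
  }, numeric(1))
  truth_curve <- vapply(1:366, function(doy) {
    sum(w[doy, ] * vapply(states, function(s) {
      latent_log_rate(doy, s, mean_age[[s]], cfg)
    }, numeric(1)))
  }, numeric(1))
  # the curve carries the random effects at their mean loading, so the
  # truth analogue must include the same average individual/year effects
  truth_curve <- truth_curve +
    mean(truth_daily$ind_effect + truth_daily$year_effect)
  err <- crv$population$fit - truth_curve
  # away from the lull and the (deliberately sharp) step transitions the
  # k = 10 smooth tracks the plateaus closely ...
  dip_doy <- cfg$true_transitions[3]
  away <- circ_doy_dist(1:366, dip_doy) > 45 &
    circ_doy_dist(1:366, cfg$true_transitions[1]) > 25 &
    circ_doy_dist(1:366, cfg$true_transitions[2]) > 25
  expect_lt(max(abs(err[away])), 0.2)
  # ... while the narrow lull itself is attenuated by the basis resolution:
  # require the fitted minimum to sit at the lull, at depth at least half
  # the generating one
  near <- which(circ_doy_dist(1:366, dip_doy) <= 45)
  fitted_min_doy <- crv$population$doy[near][which.min(crv$population$fit[near])]
  expect_lte(circ_doy_dist(fitted_min_doy, dip_doy), 12)
  shoulder <- away & circ_doy_dist(1:366, dip_doy) < 80
  dip_obs <- mean(crv$population$fit[shoulder]) -
    min(crv$population$fit[near])
  expect_gt(dip_obs, 0.45 * cfg$transition_dip$depth)
})

test_that("model comparison ranks richer structure first on state-structured data", {
  r <- fixture_rates()
  specs <- list(
    doy_only = model_spec(
      by_state = FALSE, include_state = FALSE,
      include_age_smooth = FALSE, include_group = FALSE
    ),
    with_states = model_spec(include_age_smooth = FALSE),
    with_states_dup = model_spec(include_age_smooth = FALSE)
  )
  cmp <- compare_models(specs, r)
  expect_equal(nrow(cmp), 3)
  # duplicate specifications earn identical scores
  expect_equal(
    cmp$aic[cmp$model == "with_states"],
    cmp$aic[cmp$model == "with_states_dup"],
    tolerance = 1e-8
  )
  # the state-aware model outranks the DOY-only model
  expect_lt(
    cmp$rank[cmp$model == "with_states"][1],
    cmp$rank[cmp$model == "doy_only"]
  )
  # nesting: richer model explains at least as much variance
  expect_gte(
    cmp$r_squared[cmp$model == "with_states"][1],
    cmp$r_squared[cmp$model == "doy_only"]
  )
})

test_that("tidy and glance expose the fit in broom style", {
  m <- fixture_fit()
  td <- tidy(m)
  expect_true(all(c("term", "edf", "p.value") %in% names(td)))
  tp <- tidy(m, effects = "parametric")
  expect_true(all(c("estimate", "conf.low", "conf.high") %in% names(tp)))
  ta <- tidy(m, effects = "ar")
  expect_equal(nrow(ta), 5)
  tv <- tidy(m, effects = "variance")
  expect_true(any(grepl("individual", tv$term)))
  g <- glance(m)
  expect_equal(g$nobs, nrow(m$data))
  expect_true(g$r_squared > 0 && g$r_squared < 1)
})
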