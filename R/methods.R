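# broom-style accessors and ggplot2 methods for fitted objects.

#' Tidy a fitted seasonal GAMM
#'
#' @param x An `oryx_gamm`.
#' @param effects Which block to return: `"smooth"` (per-smooth effective
#'   degrees of freedom and tests), `"parametric"` (fixed-effect
#'   coefficients), `"ar"` (autoregressive coefficients) or `"variance"`
#'   (random-effect and residual standard deviations).
#' @param conf_level Interval coverage for parametric terms.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.oryx_gamm <- function(x, effects = c("smooth", "parametric", "ar", "variance"),
                           conf_level = 0.95, ...) {
  effects <- match.arg(effects)
  sm <- summary(x$gam)
  if (effects == "smooth") {
    s <- sm$s.table
    return(tibble(
      term = rownames(s),
      edf = s[, "edf"], ref_df = s[, "Ref.df"],
      statistic = s[, "F"], p.value = s[, "p-value"]
    ))
  }
  if (effects == "parametric") {
    p <- sm$p.table
    z <- qnorm(1 - (1 - conf_level) / 2)
    return(tibble(
      term = rownames(p),
      estimate = p[, "Estimate"], std.error = p[, "Std. Error"],
      statistic = p[, 3], p.value = p[, 4],
      conf.low = p[, "Estimate"] - z * p[, "Std. Error"],
      conf.high = p[, "Estimate"] + z * p[, "Std. Error"]
    ))
  }
  if (effects == "ar") {
    return(tibble(
      term = paste0("phi_", seq_along(x$phi)),
      estimate = x$phi
    ))
  }
  x$variance_components %>% rename(term = "component", estimate = "std_dev")
}

#' One-row summary of a fitted seasonal GAMM
#'
#' @param x An `oryx_gamm`.
#' @param ... Unused.
#' @return Tibble with sample size, effective degrees of freedom, AIC,
#'   REML criterion, raw-scale variance explained, residual SD, AR order
#'   and convergence status.
#' @export
glance.oryx_gamm <- function(x, ...) {
  y <- x$data$log_rate
  tibble(
    nobs = nrow(x$data),
    n_individuals = nlevels(x$data$individual_id),
    edf = sum(x$gam$edf),
    AIC = stats::AIC(x$gam),
    REML = as.numeric(x$gam$gcv.ubre),
    r_squared = 1 - sum(x$residuals_raw^2) / sum((y - mean(y))^2),
    sigma = x$sigma,
    ar_order = length(x$phi),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Tidy a season table
#' @param x An `oryx_seasons`.
#' @param ... Unused.
#' @return The season tibble.
#' @export
tidy.oryx_seasons <- function(x, ...) {
  x$seasons
}

#' Plot a prediction curve
#'
#' Population-level predicted log movement rate over the calendar year
#' with its interval band; optionally the per-state curves.
#'
#' @param object An `oryx_curve`.
#' @param by_state Facet the per-state curves instead of the population
#'   curve?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oryx_curve <- function(object, by_state = FALSE, ...) {
  if (by_state) {
    ggplot2::ggplot(object$by_state, ggplot2::aes(x = .data$doy, y = .data$fit)) +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
        fill = "grey80"
      ) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(ggplot2::vars(.data$state)) +
      ggplot2::labs(
        x = "Day of year", y = "log movement rate (log m/h)",
        title = "Predicted log daytime movement rate by reproductive state"
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$population, ggplot2::aes(x = .data$doy, y = .data$fit)) +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
        fill = "grey80"
      ) +
      ggplot2::geom_line() +
      ggplot2::labs(
        x = "Day of year", y = "log movement rate (log m/h)",
        title = "Population-level predicted log daytime movement rate"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot delineated seasons over the prediction curve
#'
#' The population curve, the global-mean reference level, every
#' global-mean crossing, the shaded transitional periods and the season
#' boundaries.
#'
#' @param object An `oryx_seasons` produced by [delineate_seasons()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oryx_seasons <- function(object, ...) {
  if (is.null(object$curve)) {
    abort("this oryx_seasons object carries no curve; use delineate_seasons()")
  }
  pop <- object$curve$population
  shading <- object$periods %>%
    mutate(xmax = if_else(.data$end < .data$start, .data$end + 366, .data$end))
  g <- ggplot2::ggplot(pop, ggplot2::aes(x = .data$doy, y = .data$fit)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "grey85"
    ) +
    ggplot2::geom_rect(
      data = shading,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$xmax,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$level, linetype = "dotted") +
    ggplot2::geom_vline(
      xintercept = object$crossings$doy,
      colour = "grey40", linewidth = 0.2
    ) +
    ggplot2::geom_vline(
      xintercept = object$boundaries,
      colour = "firebrick", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Day of year", y = "log movement rate (log m/h)",
      title = "Season transitions at global-mean crossings"
    ) +
    ggplot2::theme_minimal()
  g
}

#' Plot daily movement rates across the calendar year
#'
#' Daily mean daytime rates per DOY (points: cross-individual daily
#' means) with a thin-plate smoothed trend.
#'
#' @param rates A rates tibble from [daily_rates()].
#' @return A ggplot.
#' @export
plot_daily_rates <- function(rates) {
  daily <- rates %>%
    group_by(.data$doy) %>%
    summarise(rate = mean(.data$rate), .groups = "drop")
  ggplot2::ggplot(daily, ggplot2::aes(x = .data$doy, y = .data$rate)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(
      method = "gam", formula = y ~ s(x, bs = "tp"), se = TRUE
    ) +
    ggplot2::labs(
      x = "Day of year", y = "mean daytime movement rate (m/h)",
      title = "Daily movement rates across the calendar year"
    ) +
    ggplot2::theme_minimal()
}
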