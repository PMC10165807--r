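#' Fit activation kinetics of photo-switched flows
#'
#' Fits the exponential activation model
#' `v(t) = vmax * (1 - exp(-t / tau_on))` to a speed trace restricted to one
#' on-interval, by nonlinear least squares jointly over `(vmax, tau_on)`
#' (or with `vmax` fixed). Initialisation: `vmax` at the trace maximum,
#' `tau_on` at the time to half-maximum divided by ln 2.
#'
#' A trace that is already at its plateau from the first point (no resolvable
#' rise) is flagged `degenerate`, with `tau_on` driven to its lower bound.
#'
#' @param trace A `speed_trace` restricted to one on-interval; times are
#'   re-zeroed to the interval start.
#' @param vmax_fixed Optional fixed plateau speed (um/s); if supplied only
#'   `tau_on` is fitted.
#' @return An `activation_fit` (class `optoflow_fit`): `params`
#'   (vmax, tau_on), `se`, `rss`, `n`, `degenerate`, `fit`.
#' @export
fit_activation <- function(trace, vmax_fixed = NULL) {
  stopifnot(is.data.frame(trace), all(c("time_s", "speed_um_s") %in%
                                        names(trace)))
  if (nrow(trace) < 5L) abort("need >= 5 points to fit activation kinetics")
  d <- tibble::tibble(t = trace$time_s - min(trace$time_s),
                      v = trace$speed_um_s)
  slope <- unname(coef(lm(v ~ t, data = d))[2L])
  if (slope < 0 && cor(d$t, d$v) < -0.5) {
    abort("trace decreases over the interval; not an activation transient")
  }
  v0 <- max(d$v)
  t_half <- d$t[which(d$v >= v0 / 2)[1L]]
  tau0 <- max(t_half / log(2), diff(range(d$t)) / 100, 1e-3)
  if (is.null(vmax_fixed)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ vmax * (1 - exp(-t / tau_on)), data = d,
                        start = list(vmax = v0, tau_on = tau0),
                        lower = c(vmax = 1e-9, tau_on = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) abort(paste0("activation fit failed: ",
                                       conditionMessage(e))))
    est <- coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) c(NA_real_, NA_real_))
    params <- c(vmax = unname(est["vmax"]), tau_on = unname(est["tau_on"]))
    se <- setNames(as.numeric(se), c("vmax", "tau_on"))
  } else {
    vmax <- vmax_fixed
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ vmax * (1 - exp(-t / tau_on)), data = d,
                        start = list(tau_on = tau0),
                        lower = c(tau_on = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) abort(paste0("activation fit failed: ",
                                       conditionMessage(e))))
    params <- c(vmax = vmax, tau_on = unname(coef(fit)["tau_on"]))
    se_t <- tryCatch(summary(fit)$coefficients["tau_on", "Std. Error"],
                     error = function(e) NA_real_)
    se <- c(vmax = NA_real_, tau_on = as.numeric(se_t))
  }
  # no resolvable rise: the first sample is already at the plateau, or the
  # fitted timescale collapsed far below the sampling interval
  dt_min <- min(diff(sort(unique(d$t))))
  degenerate <- d$v[1L] >= 0.9 * params["vmax"] ||
    params["tau_on"] <= max(1e-5, dt_min / 50)
  if (degenerate) warn("rise faster than sampling: tau_on unresolved")
  structure(list(params = params, se = se, rss = sum(residuals(fit)^2),
                 n = nrow(d), degenerate = unname(degenerate), fit = fit),
            class = c("activation_fit", "optoflow_fit"))
}

#' Fit deactivation kinetics of photo-switched flows
#'
#' Fits the logistic decay `vhat(t) = 2 / (1 + exp(t / tau_off))` to a
#' normalized off-interval speed trace (`vhat(0) = 1`, decaying to 0). The
#' trace must be normalized by the speed at deactivation; supply `v0` to
#' normalize here (conventionally the mean of the last three on-state points
#' before the transition, see [normalize_deactivation()]).
#'
#' @param trace A `speed_trace` restricted to one off-interval; times
#'   re-zeroed to the deactivation.
#' @param v0 Optional normalisation speed (um/s); if `NULL` the trace is
#'   assumed normalized already.
#' @return A `deactivation_fit` (class `optoflow_fit`): `params`
#'   (tau_off), `se`, `rss`, `n`, `fit`.
#' @export
fit_deactivation <- function(trace, v0 = NULL) {
  stopifnot(is.data.frame(trace), all(c("time_s", "speed_um_s") %in%
                                        names(trace)))
  if (nrow(trace) < 5L) abort("need >= 5 points to fit deactivation kinetics")
  d <- tibble::tibble(t = trace$time_s - min(trace$time_s),
                      v = trace$speed_um_s)
  if (!is.null(v0)) {
    check_number(v0, "v0", lower = 0, strict_lower = TRUE)
    d$v <- d$v / v0
  }
  if (unname(coef(lm(v ~ t, data = d))[2L]) > 0 && cor(d$t, d$v) > 0.5) {
    abort("trace rises over the interval; not a deactivation transient")
  }
  # initial tau from the half-crossing: vhat = 1/2 at t = tau * ln 3
  i_half <- which(d$v <= 0.5)[1L]
  tau0 <- if (is.na(i_half) || d$t[i_half] <= 0) {
    max(diff(range(d$t)) / 4, 1e-3)
  } else {
    d$t[i_half] / log(3)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ 2 / (1 + exp(t / tau_off)), data = d,
                      start = list(tau_off = tau0),
                      lower = c(tau_off = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste0("deactivation fit failed: ",
                                     conditionMessage(e))))
  se <- tryCatch(summary(fit)$coefficients["tau_off", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(params = c(tau_off = unname(coef(fit)["tau_off"])),
                 se = c(tau_off = as.numeric(se)),
                 rss = sum(residuals(fit)^2), n = nrow(d), fit = fit),
            class = c("deactivation_fit", "optoflow_fit"))
}

#' Normalisation speed at a deactivation transition
#'
#' Mean of the last `n_points` on-state speeds before time `t_off`.
#'
#' @param trace A full `speed_trace`.
#' @param t_off Deactivation time (s).
#' @param n_points Number of trailing on-state points (default 3).
#' @return Normalisation speed (um/s).
#' @export
normalize_deactivation <- function(trace, t_off, n_points = 3L) {
  before <- trace[trace$time_s < t_off, , drop = FALSE]
  if (nrow(before) < n_points) abort("too few points before the transition")
  mean(utils::tail(before$speed_um_s, n_points))
}

#' Per-cycle plateau and dark-speed summaries
#'
#' For each activation cycle: the plateau speed (median over the last half
#' of the on-interval) and the dark speed (median over the last half of the
#' following off-interval). Medians are used for robustness to PIV spikes.
#' The dark-speed trend slope comes from an ordinary linear regression of
#' dark speed against cycle start time; with a single cycle the slope is
#' undefined and flagged `NA`.
#'
#' @param trace A full `speed_trace`.
#' @param schedule The matching [illumination_schedule()].
#' @return A list with `summaries` (tibble: `cycle`, `t_start_s`,
#'   `plateau_um_s`, `dark_um_s`) and `dark_trend_um_s2` (slope, um/s per
#'   s; `NA` for a single cycle).
#' @export
cycle_summaries <- function(trace, schedule) {
  segs <- segment_cycles(schedule,
                         span = c(min(trace$time_s), max(trace$time_s) + 1e-9))
  on_idx <- which(segs$label == "on")
  if (length(on_idx) == 0L) abort("schedule contains no on-interval")
  med_last_half <- function(t0, t1) {
    mid <- (t0 + t1) / 2
    sel <- trace$time_s >= mid & trace$time_s <= t1
    if (!any(sel)) return(NA_real_)
    median(trace$speed_um_s[sel])
  }
  rows <- purrr::map_dfr(seq_along(on_idx), function(k) {
    i <- on_idx[k]
    plateau <- med_last_half(segs$t_start[i], segs$t_end[i])
    j <- if (i < nrow(segs) && segs$label[i + 1L] == "off") i + 1L else NA
    dark <- if (is.na(j)) NA_real_ else
      med_last_half(segs$t_start[j], segs$t_end[j])
    tibble::tibble(cycle = k, t_start_s = segs$t_start[i],
                   plateau_um_s = plateau, dark_um_s = dark)
  })
  with_dark <- rows[!is.na(rows$dark_um_s), ]
  slope <- if (nrow(with_dark) >= 2L) {
    unname(coef(lm(dark_um_s ~ t_start_s, data = with_dark))[2L])
  } else {
    NA_real_
  }
  list(summaries = rows, dark_trend_um_s2 = slope)
}

#' Intensity-speed response and saturation intensity
#'
#' Aggregates plateau speeds measured at different illumination intensities
#' into a mean +/- standard error response curve. The saturation intensity
#' is the smallest tested intensity whose mean speed reaches
#' `saturation_frac` (default 95%) of the sweep maximum.
#'
#' @param data A data frame with columns `intensity_uW_mm2` and
#'   `speed_um_s` (one row per replicate measurement).
#' @param saturation_frac Fraction of the maximum mean speed defining
#'   saturation (default 0.95).
#' @return An `intensity_response` list: `response` (tibble: intensity,
#'   `mean_speed_um_s`, `se`, `n`) and `saturation_uW_mm2`.
#' @export
intensity_response <- function(data, saturation_frac = 0.95) {
  stopifnot(all(c("intensity_uW_mm2", "speed_um_s") %in% names(data)))
  if (dplyr::n_distinct(data$intensity_uW_mm2) < 3L) {
    abort("need >= 3 distinct intensities")
  }
  resp <- data |>
    dplyr::group_by(.data$intensity_uW_mm2) |>
    dplyr::summarise(
      mean_speed_um_s = mean(.data$speed_um_s),
      se = stats::sd(.data$speed_um_s) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$intensity_uW_mm2)
  target <- saturation_frac * max(resp$mean_speed_um_s)
  sat <- resp$intensity_uW_mm2[resp$mean_speed_um_s >= target][1L]
  structure(list(response = resp, saturation_uW_mm2 = sat),
            class = "intensity_response")
}

#' @importFrom rlang .data
NULL
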