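#' Structure-tensor orientation field
#'
#' Computes the local filament orientation of a fluorescence frame from the
#' structure tensor: image gradients by Gaussian derivatives
#' (`sigma_grad`), tensor components smoothed with a larger Gaussian window
#' (`sigma_window`). The dominant eigenvector of the tensor points across
#' the filaments, so the reported angle is rotated by pi/2 to give the
#' filament (edge-parallel) direction, in the nematic range \[-pi/2, pi/2).
#' Coherence `(lambda1 - lambda2) / (lambda1 + lambda2)` in \[0, 1\]
#' measures how anisotropic the local texture is; texture-free (constant)
#' frames have zero coherence everywhere and their angles are unreliable.
#'
#' @param frame Numeric matrix.
#' @param sigma_grad Gradient scale (px, >= 1).
#' @param sigma_window Tensor smoothing scale (px, >= `sigma_grad`).
#' @return An `orientation_field` tibble: `x_px`, `y_px`, `theta_rad`,
#'   `coherence`.
#' @export
orientation_field <- function(frame, sigma_grad = 1, sigma_window = 4) {
  stopifnot(is.matrix(frame))
  check_number(sigma_grad, "sigma_grad", lower = 1)
  if (sigma_window < sigma_grad) abort("`sigma_window` must be >= `sigma_grad`")
  g <- gauss_kernel(sigma_grad)
  dg <- gauss_kernel(sigma_grad, deriv = TRUE)
  Ix <- conv_sep(frame, kx = dg, ky = g)    # d/dx: derivative along columns
  Iy <- conv_sep(frame, kx = g, ky = dg)
  gw <- gauss_kernel(sigma_window)
  Jxx <- conv_sep(Ix * Ix, gw, gw)
  Jyy <- conv_sep(Iy * Iy, gw, gw)
  Jxy <- conv_sep(Ix * Iy, gw, gw)
  trace <- Jxx + Jyy
  if (all(trace < 1e-12)) {
    warn("constant frame: zero coherence everywhere, angles unreliable")
  }
  theta_grad <- 0.5 * atan2(2 * Jxy, Jxx - Jyy)
  theta <- wrap_nematic(theta_grad + pi / 2)
  coh <- ifelse(trace > 1e-12,
                sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / trace, 0)
  nr <- nrow(frame); nc <- ncol(frame)
  out <- tibble::tibble(
    x_px = rep(seq_len(nc), each = nr),
    y_px = rep(seq_len(nr), times = nc),
    theta_rad = as.vector(theta),
    coherence = as.vector(coh)
  )
  attr(out, "dim_px") <- c(nr, nc)
  class(out) <- c("orientation_field", class(out))
  out
}

#' Dominant orientation of a field
#'
#' Coherence-weighted circular mean of the nematic orientation (angles
#' doubled so that theta and theta + pi agree): the field's modal director
#' angle.
#'
#' @param field An `orientation_field`.
#' @param coherence_min Minimum coherence for a pixel to contribute.
#' @return Modal angle (rad) in \[-pi/2, pi/2).
#' @export
modal_angle <- function(field, coherence_min = 0.3) {
  stopifnot(inherits(field, "orientation_field"))
  q <- field$coherence >= coherence_min
  if (!any(q)) abort("no pixels meet the coherence threshold")
  w <- field$coherence[q]^2
  th <- field$theta_rad[q]
  wrap_nematic(atan2(sum(w * sin(2 * th)), sum(w * cos(2 * th))) / 2)
}

#' Mean deviation angle from a reference director
#'
#' The mean over sufficiently coherent pixels of the absolute nematic
#' deviation `|wrap(theta - theta0)|`, where wrap maps angle differences to
#' \[-pi/2, pi/2) (orientations are equivalent modulo pi). The absolute
#' value is taken before averaging because bend deformations are
#' sign-symmetric about the initial alignment.
#'
#' @param field An `orientation_field`.
#' @param theta0 Reference (initial alignment) angle (rad).
#' @param coherence_min Minimum coherence for a pixel to qualify
#'   (default 0.3).
#' @param signed If `TRUE`, average the signed deviation instead.
#' @return Mean deviation angle (rad).
#' @export
mean_deviation_angle <- function(field, theta0 = 0, coherence_min = 0.3,
                                 signed = FALSE) {
  stopifnot(inherits(field, "orientation_field"))
  q <- field$coherence >= coherence_min
  if (!any(q)) abort("no pixels meet the coherence threshold")
  dev <- wrap_nematic(field$theta_rad[q] - theta0)
  if (signed) mean(dev) else mean(abs(dev))
}

#' Bend-angle time trace from an image sequence
#'
#' Per-frame [mean_deviation_angle()] relative to the initial alignment,
#' annotated with the illumination schedule.
#'
#' @param seq An `image_sequence`.
#' @param theta0 Initial alignment angle (rad).
#' @param schedule Optional [illumination_schedule()].
#' @param sigma_grad,sigma_window,coherence_min See [orientation_field()]
#'   and [mean_deviation_angle()].
#' @return An `angle_trace` tibble: `time_s`, `angle_rad`,
#'   `intensity_uW_mm2`.
#' @export
angle_trace <- function(seq, theta0 = 0, schedule = NULL, sigma_grad = 1,
                        sigma_window = 4, coherence_min = 0.3) {
  stopifnot(inherits(seq, "image_sequence"), n_frames(seq) >= 2L)
  dt <- attr(seq, "dt_s")
  n <- n_frames(seq)
  ang <- numeric(n)
  for (k in seq_len(n)) {
    of <- orientation_field(get_frame(seq, k), sigma_grad, sigma_window)
    ang[k] <- mean_deviation_angle(of, theta0, coherence_min)
  }
  times <- (seq_len(n) - 1) * dt
  out <- tibble::tibble(
    time_s = times,
    angle_rad = ang,
    intensity_uW_mm2 = if (is.null(schedule)) 0 else
      schedule_intensity_at(schedule, times)
  )
  class(out) <- c("angle_trace", class(out))
  out
}

#' Activated angular growth rate
#'
#' Ordinary least-squares slope of the mean deviation angle versus time over
#' an activation interval.
#'
#' @param trace An `angle_trace` restricted to one on-interval.
#' @return Growth rate (rad/s).
#' @export
growth_rate <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("time_s", "angle_rad") %in%
                                        names(trace)))
  if (nrow(trace) < 3L) abort("need >= 3 points for a growth rate")
  unname(coef(lm(angle_rad ~ time_s, data = trace))[2L])
}

#' Fit the post-deactivation angle relaxation model
#'
#' After the light is switched off, the mean bend angle follows
#' `theta(t) = exp(-t/tau) * gamma_dot * t + C * exp(-t/r)`:
#' activity-driven growth at the (fixed, separately measured) rate
#' `gamma_dot`, damped by the exponential unbinding of the light-induced
#' motor clusters (time constant `tau`), plus elastic relaxation of the
#' passive network (time constant `r`, amplitude `C`). `tau`, `r` and `C`
#' are fitted by nonlinear least squares; `tau` is initialised at 24 s, the
#' independently reported unbinding time of the light-induced dimer.
#'
#' When the two time constants are nearly degenerate (estimate correlation
#' above `ident_limit`) or `gamma_dot` is zero the unbinding term is not
#' identifiable and the fit is flagged (`identifiable = FALSE`).
#'
#' @param trace An `angle_trace` restricted to one off-interval; times are
#'   re-zeroed to the deactivation instant.
#' @param gamma_dot Fixed activated growth rate (rad/s).
#' @param tau_init,r_init Starting values (s).
#' @param ident_limit Estimate-correlation threshold for the
#'   identifiability warning (default 0.99).
#' @return A `relaxation_fit` (also class `optoflow_fit`) with elements
#'   `params` (tau, r, C), `se`, `rss`, `n`, `identifiable`, `fit`.
#' @export
fit_relaxation <- function(trace, gamma_dot, tau_init = 24, r_init = 20,
                           ident_limit = 0.99) {
  stopifnot(is.data.frame(trace), all(c("time_s", "angle_rad") %in%
                                        names(trace)))
  if (nrow(trace) < 8L) abort("need >= 8 points to fit the relaxation model")
  check_number(gamma_dot, "gamma_dot", lower = 0)
  d <- tibble::tibble(t = trace$time_s - min(trace$time_s),
                      th = trace$angle_rad)
  gd <- gamma_dot
  if (gd == 0) {
    # the unbinding term vanishes: tau is structurally unidentifiable, so
    # only the elastic decay is fitted
    warn("unbinding and elastic time constants are weakly identifiable")
    fit <- minpack.lm::nlsLM(th ~ C * exp(-t / r), data = d,
                             start = list(r = r_init,
                                          C = max(d$th[1L], 1e-6)),
                             lower = c(r = 1e-6, C = 0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    est <- coef(fit)
    se2 <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                    error = function(e) rep(NA_real_, 2L))
    return(structure(
      list(params = c(tau = NA_real_, r = unname(est["r"]),
                      C = unname(est["C"])),
           se = c(tau = NA_real_, r = unname(se2[1L]), C = unname(se2[2L])),
           gamma_dot = gd,
           rss = sum(residuals(fit)^2), n = nrow(d),
           param_correlation = NA_real_,
           identifiable = FALSE, fit = fit),
      class = c("relaxation_fit", "optoflow_fit")))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      th ~ exp(-t / tau) * gd * t + C * exp(-t / r),
      data = d,
      start = list(tau = tau_init, r = r_init, C = max(d$th[1L], 1e-6)),
      lower = c(tau = 1e-6, r = 1e-6, C = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort(paste0("relaxation fit failed: ",
                                     conditionMessage(e)))
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3L))
  corr_tr <- tryCatch({
    V <- vcov(fit)
    V["tau", "r"] / sqrt(V["tau", "tau"] * V["r", "r"])
  }, error = function(e) NA_real_)
  identifiable <- gd > 0 &&
    (is.na(corr_tr) || abs(corr_tr) <= ident_limit)
  if (!identifiable) {
    warn("unbinding and elastic time constants are weakly identifiable")
  }
  structure(
    list(params = c(tau = unname(est["tau"]), r = unname(est["r"]),
                    C = unname(est["C"])),
         se = setNames(as.numeric(se), c("tau", "r", "C")),
         gamma_dot = gd,
         rss = sum(residuals(fit)^2), n = nrow(d),
         param_correlation = corr_tr,
         identifiable = identifiable, fit = fit),
    class = c("relaxation_fit", "optoflow_fit")
  )
}

#' @importFrom stats residuals
NULL
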