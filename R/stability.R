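#' Effective activity at the confinement-dependent instability threshold
#'
#' A uniformly aligned extensile active fluid confined to an activated
#' region of length `L` (along the alignment), width `W` and chamber height
#' `H` goes unstable to bend when its effective activity reaches a
#' geometry-dependent bound:
#' \deqn{\alpha_{eff} = \pi^2 L^2 (1/L^2 + 1/W^2 + 1/H^2)^2
#'       \quad \mathrm{if}\ 1/L^2 > 1/W^2 + 1/H^2,}
#' \deqn{\alpha_{eff} = 4\pi^2 (1/W^2 + 1/H^2) \quad \mathrm{otherwise}.}
#' The two branches coincide at `1/L^2 = 1/W^2 + 1/H^2`, so the bound is
#' continuous in `L` and saturates — independent of `L` — once the region is
#' long compared to the transverse confinement. As written the bound carries
#' units of um^-2 (see the package vignette for the units discussion).
#'
#' @param L,W,H Region length, width, chamber height (um); vectorised.
#' @return Effective activity bound (um^-2).
#' @examples
#' alpha_eff(100, 100, 100)   # saturated branch: 4*pi^2 * 2e-4
#' alpha_eff(50, 400, 400)    # short-region branch
#' @export
alpha_eff <- function(L, W, H) {
  if (any(L <= 0 | W <= 0 | H <= 0)) abort("all dimensions must be > 0")
  s <- 1 / W^2 + 1 / H^2
  ifelse(1 / L^2 > s,
         pi^2 * L^2 * (1 / L^2 + s)^2,
         4 * pi^2 * s)
}

#' Fit the intensity-activity proportionality coefficient
#'
#' Assuming the light-induced active stress is proportional to the
#' illumination intensity, the threshold intensity for the bend instability
#' is `I = a * alpha_eff(L, W, H)`. The coefficient `a` is the
#' least-squares slope through the origin of threshold intensity versus
#' effective activity, inverse-variance weighted when standard errors are
#' present.
#'
#' @param data A `threshold_dataset` (columns `L_um`, `W_um`, `H_um`,
#'   `I_threshold`, optional `se`).
#' @param intercept If `TRUE`, also fit an intercept (diagnostic mode; the
#'   model itself has none).
#' @return A `stability_fit` (class `optoflow_fit`): `params` (a, and
#'   intercept if requested), `se`, `rss`, `n`.
#' @export
fit_activity_coefficient <- function(data, intercept = FALSE) {
  stopifnot(is.data.frame(data),
            all(c("L_um", "W_um", "H_um", "I_threshold") %in% names(data)))
  if (nrow(data) < 2L) abort("need >= 2 records")
  aeff <- alpha_eff(data$L_um, data$W_um, data$H_um)
  if (diff(range(aeff)) < 1e-15) {
    abort("all records share one alpha_eff; slope unidentifiable")
  }
  w <- if ("se" %in% names(data) && any(is.finite(data$se) & data$se > 0)) {
    ifelse(is.finite(data$se) & data$se > 0, 1 / data$se^2, NA_real_)
  } else {
    rep(1, nrow(data))
  }
  if (anyNA(w)) w[is.na(w)] <- min(w, na.rm = TRUE)
  d <- data.frame(I = data$I_threshold, a = aeff)
  f <- if (intercept) I ~ a else I ~ a - 1
  fit <- lm(f, data = d, weights = w)
  cf <- suppressWarnings(coef(summary(fit)))
  params <- c(a = unname(coef(fit)["a"]))
  se <- c(a = unname(cf["a", "Std. Error"]))
  if (intercept) {
    params <- c(params, intercept = unname(coef(fit)["(Intercept)"]))
    se <- c(se, intercept = unname(cf["(Intercept)", "Std. Error"]))
  }
  structure(list(params = params, se = se,
                 rss = sum(residuals(fit)^2), n = nrow(d), fit = fit),
            class = c("stability_fit", "optoflow_fit"))
}

#' Predicted threshold intensity for a geometry
#'
#' `a * alpha_eff(L, W, H)` under a fitted [fit_activity_coefficient()]
#' model; constant in `L` once `1/L^2 < 1/W^2 + 1/H^2`.
#'
#' @param L,W,H Geometry (um); vectorised.
#' @param fit A `stability_fit`.
#' @return Predicted threshold intensity (same units as the fitted data).
#' @export
predict_threshold <- function(L, W, H, fit) {
  stopifnot(inherits(fit, "stability_fit"))
  unname(fit$params["a"]) * alpha_eff(L, W, H)
}

#' Generic inverse-square scaling fit of threshold data
#'
#' The confinement dependence of the threshold intensity is also well
#' described by the phenomenological form `I = gA / L^2 + gC`; this fit is
#' the standard comparison curve for the mechanistic
#' [fit_activity_coefficient()] model.
#'
#' @param data A `threshold_dataset` with >= 2 distinct `L_um`.
#' @return A `generic_scaling_fit` (class `optoflow_fit`): `params`
#'   (gA, gC), `se`, `rss`, `n`.
#' @export
fit_generic_scaling <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("L_um", "I_threshold") %in% names(data)))
  if (dplyr::n_distinct(data$L_um) < 2L) {
    abort("need >= 2 distinct region lengths")
  }
  d <- data.frame(I = data$I_threshold, x = 1 / data$L_um^2)
  fit <- lm(I ~ x, data = d)
  cf <- suppressWarnings(coef(summary(fit)))
  structure(list(params = c(gA = unname(coef(fit)["x"]),
                            gC = unname(coef(fit)["(Intercept)"])),
                 se = c(gA = unname(cf["x", "Std. Error"]),
                        gC = unname(cf["(Intercept)", "Std. Error"])),
                 rss = sum(residuals(fit)^2), n = nrow(d), fit = fit),
            class = c("generic_scaling_fit", "optoflow_fit"))
}
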