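#' Accumulate displacement from a velocity-field series
#'
#' Eulerian accumulation at fixed grid nodes:
#' `u(t_k) = sum_{j<=k} v(t_j) * dt`. The series starts at zero displacement
#' at `t = 0`. Nodes that are invalid in a given field contribute a zero
#' increment at that step and are counted in `n_missing`. Eulerian (rather
#' than Lagrangian) accumulation matches the fixed PIV grid and is accurate
#' for small-to-moderate strains; it is an approximation for strains of
#' order one.
#'
#' @param fields List of `piv_field`s on a common grid, time-ordered.
#' @param dt Time step between fields (s).
#' @return A `displacement_series` tibble: `time_s`, `x_um`, `y_um`,
#'   `ux_um`, `uy_um`, `n_missing`.
#' @export
accumulate_displacement <- function(fields, dt) {
  stopifnot(length(fields) >= 2L)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  g0 <- fields[[1L]]
  for (f in fields[-1L]) {
    if (nrow(f) != nrow(g0) || any(abs(f$x_um - g0$x_um) > 1e-9) ||
        any(abs(f$y_um - g0$y_um) > 1e-9)) {
      abort("velocity fields are on different grids")
    }
  }
  n_nodes <- nrow(g0)
  ux <- uy <- numeric(n_nodes)
  miss <- integer(n_nodes)
  out <- vector("list", length(fields) + 1L)
  out[[1L]] <- tibble::tibble(time_s = 0, x_um = g0$x_um, y_um = g0$y_um,
                              ux_um = 0, uy_um = 0, n_missing = 0L)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    inc_x <- ifelse(f$valid, f$vx_um_s, 0) * dt
    inc_y <- ifelse(f$valid, f$vy_um_s, 0) * dt
    miss <- miss + as.integer(!f$valid)
    ux <- ux + inc_x; uy <- uy + inc_y
    out[[k + 1L]] <- tibble::tibble(time_s = k * dt, x_um = g0$x_um,
                                    y_um = g0$y_um, ux_um = ux, uy_um = uy,
                                    n_missing = miss)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "nx") <- attr(g0, "nx"); attr(res, "ny") <- attr(g0, "ny")
  attr(res, "window_um") <- attr(g0, "window_um")
  class(res) <- c("displacement_series", class(res))
  res
}

#' Region-averaged normal strain trace
#'
#' Cumulative normal strains `gamma_xx = <d ux/dx>` and
#' `gamma_yy = <d uy/dy>` from central differences of the accumulated
#' displacement on the PIV grid, averaged over the nodes of the activated
#' region after eroding it by one interrogation window (so windows
#' straddling the region edge never enter the average).
#'
#' @param disp A `displacement_series`.
#' @param region A [rect_region()].
#' @param erode_um Erosion margin (um); defaults to the PIV window size
#'   recorded in `disp`.
#' @return A `strain_trace` tibble: `time_s`, `gamma_xx`, `gamma_yy`.
#' @export
strain_trace <- function(disp, region, erode_um = NULL) {
  stopifnot(inherits(disp, "displacement_series"),
            inherits(region, "rect_region"))
  nx <- attr(disp, "nx"); ny <- attr(disp, "ny")
  erode_um <- erode_um %||% attr(disp, "window_um") %||% 0
  times <- unique(disp$time_s)
  g0 <- disp[disp$time_s == times[1L], ]
  xg <- matrix(g0$x_um, ny, nx); yg <- matrix(g0$y_um, ny, nx)
  hx <- xg[1L, 2L] - xg[1L, 1L]; hy <- yg[2L, 1L] - yg[1L, 1L]
  in_region <- matrix(
    g0$x_um >= region$x0 + erode_um &
      g0$x_um <= region$x0 + region$L - erode_um &
      g0$y_um >= region$y0 + erode_um &
      g0$y_um <= region$y0 + region$W - erode_um,
    ny, nx)
  # central differences only exist on interior nodes
  interior <- matrix(FALSE, ny, nx)
  interior[2:(ny - 1L), 2:(nx - 1L)] <- TRUE
  sel <- in_region & interior
  if (sum(sel) < 9L) abort("region contains < 3x3 grid nodes after erosion")
  per_time <- purrr::map_dfr(times, function(tt) {
    d <- disp[disp$time_s == tt, ]
    ux <- matrix(d$ux_um, ny, nx); uy <- matrix(d$uy_um, ny, nx)
    dux_dx <- matrix(NA_real_, ny, nx); duy_dy <- matrix(NA_real_, ny, nx)
    dux_dx[, 2:(nx - 1L)] <-
      (ux[, 3:nx] - ux[, 1:(nx - 2L)]) / (2 * hx)
    duy_dy[2:(ny - 1L), ] <-
      (uy[3:ny, ] - uy[1:(ny - 2L), ]) / (2 * hy)
    tibble::tibble(time_s = tt,
                   gamma_xx = mean(dux_dx[sel]),
                   gamma_yy = mean(duy_dy[sel]))
  })
  class(per_time) <- c("strain_trace", class(per_time))
  attr(per_time, "region") <- region
  per_time
}

#' Normalized region fluorescence trace
#'
#' Mean pixel intensity inside the activated region per frame, divided by
#' its first-frame value — a proxy for material flux through the region
#' boundary (filaments leaving the region carry fluorescence with them).
#'
#' @param seq An `image_sequence`.
#' @param region A [rect_region()].
#' @return A tibble: `time_s`, `intensity_rel`.
#' @export
region_intensity_trace <- function(seq, region) {
  stopifnot(inherits(seq, "image_sequence"))
  px <- attr(seq, "px_size_um"); dt <- attr(seq, "dt_s")
  d <- dim(seq)
  mask <- region_mask(region, d[1:2], px)
  if (!any(mask)) abort("region contains no pixels")
  vals <- vapply(seq_len(d[3L]),
                 function(k) mean(get_frame(seq, k)[mask]), numeric(1))
  tibble::tibble(time_s = (seq_len(d[3L]) - 1) * dt,
                 intensity_rel = vals / vals[1L])
}

#' Classify the dynamic regime of an activated region
#'
#' Three regimes are distinguished by the accumulated normal strains over
#' the activation: **buckling** when the net transverse strain change
#' `Delta gamma_yy` exceeds `eps_y` (bend deformation pushes material
#' perpendicular to the alignment); otherwise **sliding** when the final
#' extensional strain `gamma_xx` exceeds `eps_x` (filaments telescope along
#' the alignment); otherwise **quiescent**. The slow negative drift of
#' `gamma_yy` from depletion-induced contraction is not subtracted; the
#' rule is applied to the raw net change.
#'
#' @param strain A `strain_trace` spanning the activation.
#' @param eps_x,eps_y Strain thresholds (default 0.005 = 0.5%).
#' @return A length-1 character label (`"quiescent"`, `"sliding"` or
#'   `"buckling"`) with attributes `dgamma_yy` and `gamma_xx_final`.
#' @export
classify_regime <- function(strain, eps_x = 0.005, eps_y = 0.005) {
  stopifnot(is.data.frame(strain),
            all(c("gamma_xx", "gamma_yy") %in% names(strain)))
  dgyy <- strain$gamma_yy[nrow(strain)] - strain$gamma_yy[1L]
  gxx <- strain$gamma_xx[nrow(strain)]
  label <- if (dgyy > eps_y) "buckling" else if (gxx > eps_x) "sliding"
    else "quiescent"
  structure(label, dgamma_yy = dgyy, gamma_xx_final = gxx)
}

#' Threshold intensity for the bend instability
#'
#' The smallest tested intensity whose net transverse strain change over the
#' activation window exceeds `eps` (default 0.5%). Returns `NA` (with the
#' attribute `reached = FALSE`) when no intensity qualifies.
#'
#' @param results A data frame with columns `intensity_uW_mm2` and
#'   `dgamma_yy`, sorted by increasing intensity.
#' @param eps Strain threshold (default 0.005).
#' @return Threshold intensity (uW/mm^2), or `NA` if not reached.
#' @export
threshold_intensity <- function(results, eps = 0.005) {
  stopifnot(is.data.frame(results),
            all(c("intensity_uW_mm2", "dgamma_yy") %in% names(results)))
  if (nrow(results) < 2L) abort("need >= 2 intensities")
  if (is.unsorted(results$intensity_uW_mm2, strictly = FALSE)) {
    abort("`results` must be sorted by increasing intensity")
  }
  hit <- which(results$dgamma_yy > eps)
  if (length(hit) == 0L) {
    return(structure(NA_real_, reached = FALSE))
  }
  structure(results$intensity_uW_mm2[hit[1L]], reached = TRUE)
}
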