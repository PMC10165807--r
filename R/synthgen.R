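#' Synthetic filamentous texture
#'
#' Generates an anisotropic band-pass-filtered Gaussian random field that
#' mimics a flow-aligned bundled microtubule network: intensity correlations
#' are elongated along the director, giving a texture whose dominant
#' structure-tensor orientation equals `orientation`. The field is built in
#' Fourier space from seeded white noise, so frames are periodic and
#' bit-reproducible for a fixed seed.
#'
#' @param seed Integer seed.
#' @param shape Integer length-2: frame size in pixels `c(nrow, ncol)`.
#' @param orientation Director angle (rad, CCW from +x in array coordinates).
#' @param correlation_length Across-filament correlation length (um); the
#'   along-filament correlation is 6x longer. Must be >= 2 pixels.
#' @param px_size Pixel size (um).
#' @return A numeric matrix with values in \[0, 1\].
#' @examples
#' tex <- gen_texture(seed = 1, shape = c(64, 64), orientation = 0,
#'                    correlation_length = 4)
#' range(tex)
#' @export
gen_texture <- function(seed, shape = c(256L, 256L), orientation = 0,
                        correlation_length = 6, px_size = 1) {
  check_number(px_size, "px_size", lower = 0, strict_lower = TRUE)
  check_number(correlation_length, "correlation_length",
               lower = 2 * px_size)
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  stopifnot(nr >= 8L, nc >= 8L)
  ell_across <- correlation_length / px_size       # px
  ell_along <- 6 * ell_across
  with_local_seed(seed, {
    # bundle-scale anisotropic field (sets the orientation) plus fine
    # isotropic labelling speckle (gives PIV high-frequency content, as
    # fluorophore granularity does in real images)
    bundles <- grf_field(nr, nc, orientation, ell_along, ell_across)
    speckle <- grf_field(nr, nc, 0, 1.5, 1.5)
    field <- 0.65 * bundles + 0.35 * speckle
    rng <- range(field)
    (field - rng[1]) / (rng[2] - rng[1])
  })
}

# unit-variance Gaussian random field with an anisotropic Gaussian spectral
# envelope; DC removed (band-pass), periodic by construction
grf_field <- function(nr, nc, orientation, ell_par, ell_perp) {
  noise <- matrix(rnorm(nr * nc), nr, nc)
  fy <- fft_freq(nr); fx <- fft_freq(nc)           # cycles / px
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  FY <- matrix(fy, nr, nc)
  f_par <- FX * cos(orientation) + FY * sin(orientation)
  f_perp <- -FX * sin(orientation) + FY * cos(orientation)
  env <- exp(-2 * pi^2 * (ell_par^2 * f_par^2 + ell_perp^2 * f_perp^2))
  env[1L, 1L] <- 0
  field <- Re(fft(fft(noise) * env, inverse = TRUE)) / (nr * nc)
  field / sd(field)
}

fft_freq <- function(n) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / n
}

#' Programmed flow specification
#'
#' Describes the ground-truth in-plane flow used to advect synthetic
#' textures. Kinds: `uniform` (constant `c(speed, 0)`), `shear`
#' (vx = rate * (y - y0), simple shear), `extension` (vx = rate * (x - x0),
#' uniaxial extension), `bend_mode` (vy = (pi/2) * (growth/wavevector) *
#' sin(wavevector * x), a transverse undulation whose mean absolute director
#' tilt grows at `growth` rad/s), and `turbulent` (divergence-free field
#' derived from a smoothed random stream function).
#'
#' @param kind One of `"uniform"`, `"shear"`, `"extension"`, `"bend_mode"`,
#'   `"turbulent"`.
#' @param speed Speed scale (um/s); RMS speed for `turbulent`.
#' @param rate Velocity-gradient rate (1/s) for `shear`/`extension`.
#' @param wavevector Bend wavevector (rad/um).
#' @param growth Mean-angle growth rate (rad/s) for `bend_mode`.
#' @param correlation_length Stream-function correlation length (um,
#'   `turbulent`).
#' @param origin Length-2 reference point (um) for `shear`/`extension`.
#' @param seed Seed for the turbulent stream function.
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(kind = c("uniform", "shear", "extension", "bend_mode",
                               "turbulent"),
                      speed = 1, rate = 0.01, wavevector = 2 * pi / 64,
                      growth = 0.002, correlation_length = 20,
                      origin = c(0, 0), seed = 1L) {
  kind <- match.arg(kind)
  check_number(speed, "speed", lower = 0)
  if (kind == "turbulent") {
    check_number(correlation_length, "correlation_length", lower = 0,
                 strict_lower = TRUE)
  }
  structure(list(kind = kind, speed = speed, rate = rate,
                 wavevector = wavevector, growth = growth,
                 correlation_length = correlation_length,
                 origin = origin, seed = seed),
            class = "flow_spec")
}

# Velocity (um/s) of a flow_spec at positions x, y (um) for a frame of given
# pixel dimensions. Returns list(vx, vy) of the same shape as x.
flow_velocity <- function(flow, x, y, dim, px_size) {
  switch(flow$kind,
    uniform = list(vx = rep_len(flow$speed, length(x)),
                   vy = numeric(length(x))),
    shear = list(vx = flow$rate * (y - flow$origin[2]),
                 vy = numeric(length(x))),
    extension = list(vx = flow$rate * (x - flow$origin[1]),
                     vy = numeric(length(x))),
    bend_mode = list(vx = numeric(length(x)),
                     vy = (pi / 2) * (flow$growth / flow$wavevector) *
                       sin(flow$wavevector * (x - flow$origin[1]))),
    turbulent = turbulent_velocity(flow, x, y, dim, px_size)
  )
}

# Divergence-free random flow: v = speed * (d psi/dy, -d psi/dx) / rms,
# with psi a periodic Gaussian random field of the given correlation length.
turbulent_velocity <- function(flow, x, y, dim, px_size) {
  nr <- dim[1L]; nc <- dim[2L]
  ell <- flow$correlation_length / px_size
  psi <- with_local_seed(flow$seed, {
    noise <- matrix(rnorm(nr * nc), nr, nc)
    fy <- fft_freq(nr); fx <- fft_freq(nc)
    env <- exp(-2 * pi^2 * ell^2 *
                 (matrix(fx^2, nr, nc, byrow = TRUE) + matrix(fy^2, nr, nc)))
    env[1L, 1L] <- 0
    Re(fft(fft(noise) * env, inverse = TRUE)) / (nr * nc)
  })
  # central differences with periodic wrap (psi is periodic by construction)
  up <- psi[c(nr, seq_len(nr - 1L)), ]; dn <- psi[c(seq_len(nr - 1L) + 1L, 1L), ]
  lf <- psi[, c(nc, seq_len(nc - 1L))]; rt <- psi[, c(seq_len(nc - 1L) + 1L, 1L)]
  dpsy <- (dn - up) / (2 * px_size)
  dpsx <- (rt - lf) / (2 * px_size)
  rms <- sqrt(mean(dpsy^2 + dpsx^2) / 2)
  vx_grid <- flow$speed * dpsy / rms
  vy_grid <- -flow$speed * dpsx / rms
  cx <- x / px_size + 1; cy <- y / px_size + 1
  list(vx = bilinear_sample(vx_grid, cx, cy, "periodic"),
       vy = bilinear_sample(vy_grid, cx, cy, "periodic"))
}

#' Render a synthetic image sequence
#'
#' Advects a texture by the time-integrated programmed flow, gated by an
#' illumination schedule: pixels inside the active region move while the
#' light is on and are frozen otherwise; pixels outside the region are always
#' static. Warping is a backward map with bilinear interpolation of the
#' integrated displacement, so intensity is conserved under pure translation
#' up to boundary handling and noise. Additive Gaussian camera noise is drawn
#' per frame from the given seed.
#'
#' @param texture Base frame (matrix from [gen_texture()]).
#' @param flow A [flow_spec()].
#' @param schedule An [illumination_schedule()]; on-episodes define when (and
#'   through their `region`, where) the material moves.
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame interval (s).
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param seed Integer seed for the noise.
#' @param px_size Pixel size (um).
#' @param boundary Warp boundary handling: `"periodic"` (default; textures
#'   are periodic by construction) or `"clamp"`.
#' @param relax_r Optional elastic relaxation time (s): when set, the
#'   accumulated displacement decays as `exp(-t'/relax_r)` after each off
#'   transition, emulating the elastic recovery of the passive network. By
#'   default (`NULL`) frames are strictly static while the light is off.
#' @param background_dim Optional factor in \[0, 1): when set and the
#'   schedule activates a sub-region, material flowing into the region from
#'   outside carries this fraction of the background intensity, so sustained
#'   outflow visibly drains the region (emulating expelled filaments that do
#'   not return). By default (`NULL`) advection conserves intensity.
#' @return An `image_sequence`: numeric array `[row, col, frame]` with
#'   attributes `px_size_um` and `dt_s`.
#' @export
render_sequence <- function(texture, flow, schedule, n_frames, dt,
                            noise_sd = 0, seed = 1L, px_size = 1,
                            boundary = c("periodic", "clamp"),
                            relax_r = NULL, background_dim = NULL) {
  boundary <- match.arg(boundary)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  stopifnot(is.matrix(texture), n_frames >= 2L)
  stopifnot(inherits(schedule, "illumination_schedule"))
  nr <- nrow(texture); nc <- ncol(texture)
  on_eps <- schedule[schedule$intensity > 0, , drop = FALSE]
  region <- if (nrow(on_eps) > 0L) on_eps$region[[1L]] else NULL
  if (!is.null(region)) {
    if (region$x0 < 0 || region$y0 < 0 ||
        region$x0 + region$L > nc * px_size ||
        region$y0 + region$W > nr * px_size) {
      abort("activation region lies outside the frame")
    }
  }
  mask <- region_mask(region, c(nr, nc), px_size)
  src_tex <- texture
  if (!is.null(background_dim) && !is.null(region)) {
    check_number(background_dim, "background_dim", lower = 0, upper = 1)
    src_tex[!mask] <- background_dim * texture[!mask]
  }
  x_um <- matrix((seq_len(nc) - 1) * px_size, nr, nc, byrow = TRUE)
  y_um <- matrix((seq_len(nr) - 1) * px_size, nr, nc)
  vel <- flow_velocity(flow, as.vector(x_um), as.vector(y_um),
                       c(nr, nc), px_size)
  frames <- array(0, dim = c(nr, nc, n_frames))
  times <- (seq_len(n_frames) - 1) * dt
  noise <- with_local_seed(seed, {
    array(rnorm(nr * nc * n_frames, sd = max(noise_sd, 0)),
          dim = c(nr, nc, n_frames))
  })
  if (noise_sd <= 0) noise[] <- 0
  for (k in seq_len(n_frames)) {
    t_eff <- effective_time(on_eps, times[k], relax_r)
    if (t_eff <= 0) {
      warped <- texture
    } else if (flow$kind == "bend_mode") {
      uy <- bend_displacement(flow, (seq_len(nc) - 1) * px_size, t_eff)
      src_x <- as.vector(x_um) / px_size + 1
      src_y <- (as.vector(y_um) - rep(uy, each = nr)) / px_size + 1
      warped <- matrix(bilinear_sample(src_tex, src_x, src_y, boundary),
                       nr, nc)
    } else {
      src_x <- (as.vector(x_um) - vel$vx * t_eff) / px_size + 1
      src_y <- (as.vector(y_um) - vel$vy * t_eff) / px_size + 1
      warped <- matrix(bilinear_sample(src_tex, src_x, src_y, boundary),
                       nr, nc)
    }
    fr <- texture
    fr[mask] <- warped[mask]
    frames[, , k] <- fr + noise[, , k]
  }
  image_sequence(frames, px_size = px_size, dt = dt)
}

# Transverse displacement profile of the bend mode at activated time T:
# the local director tilt is programmed directly as
# tilt(x) = (pi/2) * growth * T * sin(k x), whose mean absolute value is
# exactly growth * T, and the displacement is the integrated tangent
# uy(x) = int tan(tilt) dx (tilt clamped short of pi/2).
bend_displacement <- function(flow, x_um, t_eff) {
  tilt <- (pi / 2) * flow$growth * t_eff *
    sin(flow$wavevector * (x_um - flow$origin[1]))
  tilt <- pmax(pmin(tilt, 1.45), -1.45)
  dx <- c(0, diff(x_um))
  cumsum(tan(tilt) * dx)
}

# effective advection time at clock time t: the total illuminated time, with
# optional exponential decay of the accumulated displacement after each off
# transition (elastic recovery)
effective_time <- function(on_eps, t, relax_r = NULL) {
  t_on <- active_time(on_eps, t)
  if (is.null(relax_r) || nrow(on_eps) == 0L) return(t_on)
  last_end <- suppressWarnings(max(on_eps$t_end[on_eps$t_start <= t]))
  in_off <- !any(on_eps$t_start <= t & on_eps$t_end > t)
  if (is.finite(last_end) && in_off && t > last_end) {
    t_on * exp(-(t - last_end) / relax_r)
  } else {
    t_on
  }
}

# total illuminated time in [0, t] under the on-episodes
active_time <- function(on_eps, t) {
  if (nrow(on_eps) == 0L) return(0)
  sum(pmax(0, pmin(on_eps$t_end, t) - pmin(on_eps$t_start, t)))
}

#' Image sequence container
#'
#' @param frames Numeric array `[row, col, frame]` or list of matrices.
#' @param px_size Pixel size (um).
#' @param dt Frame interval (s).
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, px_size, dt) {
  if (is.list(frames)) {
    frames <- array(unlist(frames),
                    dim = c(dim(frames[[1L]]), length(frames)))
  }
  stopifnot(length(dim(frames)) == 3L)
  structure(frames, px_size_um = px_size, dt_s = dt,
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_sequence> %d frames of %dx%d px (%.3g um/px, dt=%.3g s)\n",
              d[3], d[1], d[2], attr(x, "px_size_um"), attr(x, "dt_s")))
  invisible(x)
}

n_frames <- function(seq) dim(seq)[3L]
get_frame <- function(seq, k) {
  f <- seq[, , k]
  dim(f) <- dim(seq)[1:2]
  f
}

#' Synthetic photoswitching speed trace
#'
#' Generates the mean flow speed of an opto-kinesin network through dark and
#' light cycles. Within each on-episode the noiseless mean rises as
#' `dark_speed + (vmax - dark_speed) * (1 - exp(-t'/tau_on))`; after each off
#' transition it follows a normalized logistic decay
#' `dark_speed + (v_deact - dark_speed) * 2 / (1 + exp(t'/tau_off))` toward
#' the dark speed, where `v_deact` is the speed at deactivation. If the trace
#' begins in the dark after no prior activation the decay starts from `vmax`
#' (a deactivation at t = 0), which yields pure normalized decay traces when
#' `vmax = 1, dark_speed = 0`.
#'
#' @param vmax Plateau speed in the light (um/s); must exceed `dark_speed`.
#' @param tau_on,tau_off Activation/deactivation time constants (s).
#' @param dark_speed Residual dark-state speed (um/s).
#' @param schedule An [illumination_schedule()].
#' @param noise_sd Additive Gaussian noise sd (um/s).
#' @param seed Integer seed.
#' @param dt Sampling interval (s).
#' @param span Optional time span to sample; defaults to the schedule extent.
#' @param dark_creep Linear drift of the dark speed (um/s per s, default 0) —
#'   emulates the slow rise of dark-state flows over a sample's lifetime.
#' @return A `speed_trace` tibble: `time_s`, `speed_um_s`,
#'   `intensity_uW_mm2`.
#' @export
gen_speed_trace <- function(vmax, tau_on, tau_off, dark_speed = 0, schedule,
                            noise_sd = 0, seed = 1L, dt = 1, span = NULL,
                            dark_creep = 0) {
  check_number(vmax, "vmax", lower = 0, strict_lower = TRUE)
  check_number(tau_on, "tau_on", lower = 0, strict_lower = TRUE)
  check_number(tau_off, "tau_off", lower = 0, strict_lower = TRUE)
  check_number(dark_speed, "dark_speed", lower = 0)
  if (vmax <= dark_speed) abort("`vmax` must exceed `dark_speed`")
  segs <- segment_cycles(schedule, span = span)
  times <- seq(segs$t_start[1], max(segs$t_end), by = dt)
  v <- numeric(length(times))
  v_deact <- vmax   # decay starts from vmax if the trace opens in the dark
  for (i in seq_len(nrow(segs))) {
    # segments are half-open [t_start, t_end); the final sample belongs to
    # the last segment
    idx <- which(times >= segs$t_start[i] - 1e-9 &
                   (times < segs$t_end[i] - 1e-9 |
                      (i == nrow(segs) & times <= segs$t_end[i] + 1e-9)))
    tp <- times[idx] - segs$t_start[i]
    dark_i <- dark_speed + dark_creep * segs$t_start[i]
    if (segs$label[i] == "on") {
      v[idx] <- dark_i + (vmax - dark_i) * (1 - exp(-tp / tau_on))
      t_len <- segs$t_end[i] - segs$t_start[i]
      v_deact <- dark_i + (vmax - dark_i) * (1 - exp(-t_len / tau_on))
    } else {
      v[idx] <- dark_i + (v_deact - dark_i) * 2 / (1 + exp(tp / tau_off))
    }
  }
  noise <- with_local_seed(seed, rnorm(length(v), sd = max(noise_sd, 0)))
  if (noise_sd <= 0) noise[] <- 0
  out <- tibble::tibble(
    time_s = times,
    speed_um_s = v + noise,
    intensity_uW_mm2 = schedule_intensity_at(schedule, times)
  )
  class(out) <- c("speed_trace", class(out))
  out
}

#' Synthetic bend-angle trace
#'
#' Generates the mean in-plane deviation angle of a photo-activated aligned
#' network. During on-episodes the angle grows linearly at `gamma_dot`;
#' after each off transition it relaxes as
#' `theta(t') = exp(-t'/tau) * gamma_dot * t' + C * exp(-t'/r)`,
#' combining continued growth damped by motor-cluster unbinding (time
#' constant `tau`) with elastic network recovery (time constant `r`); `C`
#' defaults to the angle at deactivation so the trace is continuous.
#'
#' @param gamma_dot Activated angular growth rate (rad/s).
#' @param tau Motor unbinding time constant (s).
#' @param r Elastic relaxation time constant (s).
#' @param C Relaxation amplitude (rad) for an initial off-interval; by
#'   default the angle at the preceding deactivation.
#' @param schedule An [illumination_schedule()].
#' @param noise_sd Additive Gaussian noise sd (rad).
#' @param seed Integer seed.
#' @param dt Sampling interval (s).
#' @param span Optional time span; defaults to the schedule extent.
#' @return An `angle_trace` tibble: `time_s`, `angle_rad`,
#'   `intensity_uW_mm2`.
#' @export
gen_angle_trace <- function(gamma_dot, tau, r, C = NULL, schedule,
                            noise_sd = 0, seed = 1L, dt = 1, span = NULL) {
  check_number(gamma_dot, "gamma_dot", lower = 0)
  check_number(tau, "tau", lower = 0, strict_lower = TRUE)
  check_number(r, "r", lower = 0, strict_lower = TRUE)
  segs <- segment_cycles(schedule, span = span)
  times <- seq(segs$t_start[1], max(segs$t_end), by = dt)
  th <- numeric(length(times))
  theta_now <- 0
  for (i in seq_len(nrow(segs))) {
    idx <- which(times >= segs$t_start[i] - 1e-9 &
                   (times < segs$t_end[i] - 1e-9 |
                      (i == nrow(segs) & times <= segs$t_end[i] + 1e-9)))
    tp <- times[idx] - segs$t_start[i]
    t_len <- segs$t_end[i] - segs$t_start[i]
    if (segs$label[i] == "on") {
      th[idx] <- theta_now + gamma_dot * tp
      theta_now <- theta_now + gamma_dot * t_len
    } else {
      C_i <- if (i == 1L && !is.null(C)) C else theta_now
      th[idx] <- exp(-tp / tau) * gamma_dot * tp + C_i * exp(-tp / r)
      theta_now <- exp(-t_len / tau) * gamma_dot * t_len +
        C_i * exp(-t_len / r)
    }
  }
  noise <- with_local_seed(seed, rnorm(length(th), sd = max(noise_sd, 0)))
  if (noise_sd <= 0) noise[] <- 0
  out <- tibble::tibble(
    time_s = times,
    angle_rad = th + noise,
    intensity_uW_mm2 = schedule_intensity_at(schedule, times)
  )
  class(out) <- c("angle_trace", class(out))
  out
}

#' Synthetic instability-threshold dataset
#'
#' For each activation geometry (L, W, H) the threshold intensity is
#' `I* = a * alpha_eff(L, W, H) * (1 + eps)` with multiplicative Gaussian
#' noise `eps ~ N(0, rel_noise)`; the noiseless dataset satisfies the
#' confinement model exactly.
#'
#' @param a Intensity-activity proportionality coefficient (intensity per
#'   um^-2 of effective activity).
#' @param geometries A data frame with columns `L_um`, `W_um`, `H_um` (um).
#' @param rel_noise Relative noise sd (fraction).
#' @param seed Integer seed.
#' @return A `threshold_dataset` tibble: `L_um`, `W_um`, `H_um`,
#'   `I_threshold`, `se`, `n`.
#' @export
gen_threshold_dataset <- function(a, geometries, rel_noise = 0, seed = 1L) {
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  check_number(rel_noise, "rel_noise", lower = 0)
  geometries <- tibble::as_tibble(geometries)
  stopifnot(all(c("L_um", "W_um", "H_um") %in% names(geometries)))
  if (any(geometries$L_um <= 0 | geometries$W_um <= 0 | geometries$H_um <= 0)) {
    abort("all dimensions must be > 0")
  }
  aeff <- alpha_eff(geometries$L_um, geometries$W_um, geometries$H_um)
  eps <- with_local_seed(seed, rnorm(length(aeff), sd = max(rel_noise, 0)))
  if (rel_noise <= 0) eps[] <- 0
  out <- dplyr::mutate(geometries,
                       I_threshold = a * aeff * (1 + eps),
                       se = NA_real_, n = 1L)
  class(out) <- c("threshold_dataset", class(out))
  out
}
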