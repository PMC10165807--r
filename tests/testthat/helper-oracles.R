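# Independent oracles and small fixture builders shared across tests.

# Exact subpixel image translation via the Fourier shift theorem (periodic).
fourier_shift <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  ffr <- function(n) c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n
  ph <- exp(-2i * pi * (outer(ffr(nr), rep(1, nc)) * dy +
                          outer(rep(1, nr), ffr(nc)) * dx))
  Re(fft(fft(img) * ph, inverse = TRUE)) / (nr * nc)
}

# Rotate an image by phi (CCW in array coordinates) about its centre with
# bilinear resampling; used only as a test oracle.
rotate_image <- function(img, phi) {
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  g <- expand.grid(y = seq_len(nr), x = seq_len(nc))
  xs <- cx + cos(phi) * (g$x - cx) + sin(phi) * (g$y - cy)
  ys <- cy - sin(phi) * (g$x - cx) + cos(phi) * (g$y - cy)
  xs <- pmin(pmax(xs, 1), nc); ys <- pmin(pmax(ys, 1), nr)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  x1 <- pmin(x0 + 1, nc); y1 <- pmin(y0 + 1, nr)
  v <- (1 - fy) * ((1 - fx) * img[cbind(y0, x0)] + fx * img[cbind(y0, x1)]) +
    fy * ((1 - fx) * img[cbind(y1, x0)] + fx * img[cbind(y1, x1)])
  matrix(v, nr, nc)
}

# Sinusoidal stripe pattern whose filaments run at angle `ang` (CCW from x).
stripes <- function(n = 64, ang = 0, period = 8) {
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  matrix(sin(2 * pi * (-sin(ang) * g$x + cos(ang) * g$y) / period), n, n)
}

# Orientation field fixture with prescribed angles/coherence.
make_orientation_field <- function(theta, coherence = 1) {
  n <- length(theta)
  out <- tibble::tibble(x_px = seq_len(n), y_px = 1L,
                        theta_rad = theta,
                        coherence = rep_len(coherence, n))
  class(out) <- c("orientation_field", class(out))
  out
}

# Uniform-velocity piv_field fixture on an nx x ny grid.
make_piv_field <- function(vx, vy, nx = 7, ny = 7, step = 16, valid = TRUE) {
  out <- tibble::tibble(
    x_um = rep((seq_len(nx) - 1) * step, each = ny),
    y_um = rep((seq_len(ny) - 1) * step, times = nx),
    vx_um_s = rep_len(vx, nx * ny),
    vy_um_s = rep_len(vy, nx * ny),
    valid = rep_len(valid, nx * ny)
  )
  attr(out, "nx") <- nx; attr(out, "ny") <- ny
  attr(out, "window_um") <- 32; attr(out, "step_um") <- step
  attr(out, "dt_s") <- 1; attr(out, "timestamp_s") <- NA_real_
  class(out) <- c("piv_field", class(out))
  out
}

always_on <- function(intensity = 1, region = NULL) {
  illumination_schedule(0, 1e7, intensity, region = region)
}
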