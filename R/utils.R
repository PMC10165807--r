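# Internal numeric helpers shared across modules.
#
# Image axis convention used throughout the package: matrices are indexed
# [row, col] with row = y (increasing downward) and col = x (increasing
# rightward); x is the initial filament alignment direction. Pixel centers
# sit at integer coordinates (1-based). All times are seconds, lengths um,
# intensities uW/mm^2 at module boundaries.

#' @importFrom rlang abort warn inform `%||%`
#' @importFrom stats median sd lm coef rnorm runif fft nextn mvfft setNames
#'   complete.cases cor quantile vcov approx
NULL

gauss_kernel <- function(sigma, deriv = FALSE) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (deriv) {
    # derivative of the Gaussian: d/dx, normalised so a unit ramp has slope 1
    k <- -x * g / sigma^2
    k <- k / sum(-x * k)
    return(k)
  }
  g
}

# Separable convolution with replicate (edge-clamp) padding.  `kx` runs along
# columns (x), `ky` along rows (y).
conv_sep <- function(img, kx, ky) {
  out <- conv_axis(img, ky, axis = 1L)
  conv_axis(out, kx, axis = 2L)
}

conv_axis <- function(img, k, axis) {
  r <- (length(k) - 1L) %/% 2L
  n <- dim(img)[axis]
  idx_pad <- pmin(pmax(seq(1L - r, n + r), 1L), n)
  if (axis == 1L) {
    pad <- img[idx_pad, , drop = FALSE]
    out <- matrix(0, nrow(img), ncol(img))
    for (i in seq_along(k)) {
      out <- out + k[i] * pad[seq_len(nrow(img)) + (i - 1L), , drop = FALSE]
    }
  } else {
    pad <- img[, idx_pad, drop = FALSE]
    out <- matrix(0, nrow(img), ncol(img))
    for (i in seq_along(k)) {
      out <- out + k[i] * pad[, seq_len(ncol(img)) + (i - 1L), drop = FALSE]
    }
  }
  out
}

# Bilinear sampling of `img` at fractional (x = col, y = row) positions.
# boundary: "clamp" replicates edge pixels, "periodic" wraps.
bilinear_sample <- function(img, x, y, boundary = c("periodic", "clamp")) {
  boundary <- match.arg(boundary)
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  wrap <- function(i, n) {
    if (boundary == "periodic") ((i - 1L) %% n) + 1L else pmin(pmax(i, 1L), n)
  }
  c1 <- wrap(x0, nc); c2 <- wrap(x0 + 1, nc)
  r1 <- wrap(y0, nr); r2 <- wrap(y0 + 1, nr)
  v11 <- img[cbind(r1, c1)]; v12 <- img[cbind(r1, c2)]
  v21 <- img[cbind(r2, c1)]; v22 <- img[cbind(r2, c2)]
  (1 - fy) * ((1 - fx) * v11 + fx * v12) + fy * ((1 - fx) * v21 + fx * v22)
}

# Run `expr` under a local RNG state seeded with `seed`; restores the caller's
# RNG afterwards so generators never perturb user code.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s.", name, format(lower)))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s.", name, format(lower)))
  }
  if (x > upper) abort(sprintf("`%s` must be <= %s.", name, format(upper)))
  invisible(x)
}

# Wrap angle differences into the nematic range [-pi/2, pi/2).
wrap_nematic <- function(theta) {
  ((theta + pi / 2) %% pi) - pi / 2
}
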