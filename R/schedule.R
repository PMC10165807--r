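#' Illumination schedules and activation regions
#'
#' An illumination schedule lists the photo-activation episodes applied to a
#' sample: non-overlapping, time-ordered intervals with a light intensity
#' (uW/mm^2) and, optionally, a rectangular activation region. Times outside
#' every episode (or inside an episode with zero intensity) are dark.
#'
#' @param t_start,t_end Numeric vectors of episode start/end times (s).
#' @param intensity Numeric vector of episode intensities (uW/mm^2), recycled.
#' @param region A [rect_region()] applied to all episodes, or a list of
#'   regions (one per episode, `NULL` = full frame).
#'
#' @return A tibble of class `illumination_schedule` with columns `t_start`,
#'   `t_end`, `intensity` and a list-column `region`.
#' @examples
#' illumination_schedule(t_start = c(0, 900), t_end = c(600, 1500),
#'                       intensity = 1)
#' @export
illumination_schedule <- function(t_start, t_end, intensity = 1,
                                  region = NULL) {
  if (length(t_start) == 0L) abort("schedule must contain >= 1 episode")
  if (length(t_end) != length(t_start)) {
    abort("`t_start` and `t_end` must have equal length")
  }
  intensity <- rep_len(intensity, length(t_start))
  if (any(t_end <= t_start)) abort("every episode needs `t_end` > `t_start`")
  if (any(intensity < 0)) abort("`intensity` must be >= 0")
  ord <- order(t_start)
  t_start <- t_start[ord]; t_end <- t_end[ord]; intensity <- intensity[ord]
  if (length(t_start) > 1L &&
      any(t_start[-1L] < t_end[-length(t_end)] - 1e-9)) {
    abort("episodes must be non-overlapping")
  }
  if (is.null(region) || inherits(region, "rect_region")) {
    region <- rep(list(region), length(t_start))
  }
  stopifnot(length(region) == length(t_start))
  out <- tibble::tibble(t_start = as.numeric(t_start),
                        t_end = as.numeric(t_end),
                        intensity = as.numeric(intensity),
                        region = region)
  class(out) <- c("illumination_schedule", class(out))
  out
}

#' Rectangular activation region
#'
#' Regions are axis-aligned rectangles in the image plane, specified in um
#' with `x0`, `y0` the top-left corner, `L` the extent along the initial
#' alignment direction (x) and `W` the in-plane extent perpendicular to it.
#'
#' @param x0,y0 Top-left corner (um).
#' @param L,W Extents along x and y (um); both must be positive.
#' @return An object of class `rect_region`.
#' @export
rect_region <- function(x0, y0, L, W) {
  check_number(x0, "x0"); check_number(y0, "y0")
  check_number(L, "L", lower = 0, strict_lower = TRUE)
  check_number(W, "W", lower = 0, strict_lower = TRUE)
  structure(list(x0 = x0, y0 = y0, L = L, W = W), class = "rect_region")
}

#' @export
print.rect_region <- function(x, ...) {
  cat(sprintf("<rect_region> x0=%g, y0=%g um; L=%g x W=%g um\n",
              x$x0, x$y0, x$L, x$W))
  invisible(x)
}

# Logical mask of region pixels for a frame of `dim` = c(nrow, ncol) at
# `px_size` um/px.  Half-open in pixel space: a pixel whose centre (1-based,
# um = (index - 1) * px_size) falls in [x0, x0+L) x [y0, y0+W) is inside.
region_mask <- function(region, dim, px_size) {
  nr <- dim[1L]; nc <- dim[2L]
  if (is.null(region)) return(matrix(TRUE, nr, nc))
  x_um <- (seq_len(nc) - 1) * px_size
  y_um <- (seq_len(nr) - 1) * px_size
  in_x <- x_um >= region$x0 & x_um < region$x0 + region$L
  in_y <- y_um >= region$y0 & y_um < region$y0 + region$W
  outer(in_y, in_x, `&`)
}

#' Illumination intensity at given times
#'
#' @param schedule An [illumination_schedule()].
#' @param times Numeric vector of times (s).
#' @return Numeric vector of intensities (uW/mm^2); 0 outside all episodes.
#' @export
schedule_intensity_at <- function(schedule, times) {
  stopifnot(inherits(schedule, "illumination_schedule"))
  out <- numeric(length(times))
  for (i in seq_len(nrow(schedule))) {
    hit <- times >= schedule$t_start[i] & times < schedule$t_end[i]
    out[hit] <- schedule$intensity[i]
  }
  out
}

#' Segment a schedule into alternating on/off cycles
#'
#' Splits the time span into alternating illuminated ("on") and dark ("off")
#' intervals using only the schedule (never the data). Episodes with zero
#' intensity count as dark, as do gaps between episodes.
#'
#' @param schedule An [illumination_schedule()].
#' @param span Optional numeric length-2 time span (s) to cover; defaults to
#'   the schedule's own extent.
#' @return A tibble with columns `label` ("on"/"off"), `t_start`, `t_end`,
#'   `intensity` (episode intensity for on-intervals, 0 for off).
#' @export
segment_cycles <- function(schedule, span = NULL) {
  stopifnot(inherits(schedule, "illumination_schedule"))
  on <- schedule[schedule$intensity > 0, , drop = FALSE]
  span <- span %||% c(min(schedule$t_start), max(schedule$t_end))
  stopifnot(length(span) == 2L, span[2] > span[1])
  segs <- list()
  cursor <- span[1]
  for (i in seq_len(nrow(on))) {
    s <- max(on$t_start[i], span[1]); e <- min(on$t_end[i], span[2])
    if (e <= s) next
    if (s > cursor + 1e-9) {
      segs[[length(segs) + 1L]] <- list("off", cursor, s, 0)
    }
    segs[[length(segs) + 1L]] <- list("on", s, e, on$intensity[i])
    cursor <- e
  }
  if (cursor < span[2] - 1e-9) {
    segs[[length(segs) + 1L]] <- list("off", cursor, span[2], 0)
  }
  if (length(segs) == 0L) {
    segs[[1L]] <- list("off", span[1], span[2], 0)
  }
  tibble::tibble(
    label = vapply(segs, `[[`, character(1), 1L),
    t_start = vapply(segs, `[[`, numeric(1), 2L),
    t_end = vapply(segs, `[[`, numeric(1), 3L),
    intensity = vapply(segs, `[[`, numeric(1), 4L)
  )
}
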