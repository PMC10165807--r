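#' Read and write image sequences as multi-page TIFF
#'
#' Frames are stored as 16-bit grayscale pages; values are clipped to
#' \[0, 1\] on write and round-trip losslessly at 16-bit quantisation.
#'
#' @param seq An `image_sequence`.
#' @param path Output file.
#' @return `write_sequence` returns `path` invisibly; `read_sequence`
#'   returns an `image_sequence`.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  frames <- lapply(seq_len(n_frames(seq)), function(k) {
    f <- get_frame(seq, k)
    pmin(pmax(f, 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_sequence
#' @param px_size Pixel size (um) to attach on read.
#' @param dt Frame interval (s) to attach on read.
#' @export
read_sequence <- function(path, px_size = 1, dt = 1) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e)
                       abort(paste0("malformed TIFF '", path, "': ",
                                    conditionMessage(e))))
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0L) abort(paste0("empty image sequence: ", path))
  image_sequence(frames, px_size = px_size, dt = dt)
}

trace_schemas <- list(
  speed_trace = c("time_s", "speed_um_s", "intensity_uW_mm2"),
  angle_trace = c("time_s", "angle_rad", "intensity_uW_mm2"),
  strain_trace = c("time_s", "gamma_xx", "gamma_yy"),
  threshold_dataset = c("L_um", "W_um", "H_um", "I_threshold", "se", "n"),
  piv_field = c("x_um", "y_um", "vx_um_s", "vy_um_s", "valid")
)

#' Write a trace, field or dataset as CSV
#'
#' @param x A `speed_trace`, `angle_trace`, `strain_trace`,
#'   `threshold_dataset` or `piv_field`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  readr::write_csv(as.data.frame(x), path)
  invisible(path)
}

#' Read a trace, field or dataset from CSV with schema validation
#'
#' @param path CSV file.
#' @param type One of `"speed_trace"`, `"angle_trace"`, `"strain_trace"`,
#'   `"threshold_dataset"`, `"piv_field"`.
#' @return A tibble carrying the corresponding class.
#' @export
read_trace <- function(path, type = names(trace_schemas)) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- trace_schemas[[type]]
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    abort(paste0("CSV '", path, "' is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  class(x) <- c(type, class(x))
  x
}

#' Read or write a run configuration file
#'
#' Configurations are YAML mappings whose keys mirror the pipeline's stage
#' parameters; they round-trip losslessly through serialisation.
#'
#' @param path YAML file.
#' @return `read_config` returns a named list; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config A named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
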