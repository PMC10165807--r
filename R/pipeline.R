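#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order
#' (`simulate` -> `piv` -> `kinetics` / `orient` / `strain` ->
#' `stability`), persisting every intermediate under
#' `config$output_dir` and returning a run report that records the
#' parameters used, the files written and any warnings — enough to
#' reproduce the run bit-for-bit given the same inputs.
#'
#' The configuration is a named list (or path to a YAML file, see
#' [read_config()]) with one entry per stage; a stage runs iff its entry is
#' present. Every random operation must receive an explicit seed: a
#' `simulate` stage without `seed` fails validation.
#'
#' @param config Named list or path to a YAML config.
#' @return A `run_report` list: `stages`, `params`, `files`, `warnings`,
#'   `version`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  out_dir <- config$output_dir %||% abort("config needs `output_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = character(), params = list(), files = character(),
                 warnings = character(),
                 version = as.character(utils::packageVersion("optoflow")),
                 config_hash = rlang::hash(config))
  note <- function(stage, params, files) {
    report$stages <<- c(report$stages, stage)
    report$params[[stage]] <<- params
    report$files <<- c(report$files, files)
  }
  seq_path <- file.path(out_dir, "sequence.tif")
  schedule <- NULL
  px_size <- config$px_size %||% 1
  dt <- config$dt %||% 1

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (is.null(sim$seed)) abort("`simulate` stage requires an explicit seed")
    schedule <- config_schedule(sim$schedule)
    tex_par <- sim$texture %||% list()
    tex <- gen_texture(
      seed = sim$seed,
      shape = unlist(tex_par$shape %||% c(128L, 128L)),
      orientation = tex_par$orientation %||% 0,
      correlation_length = tex_par$correlation_length %||% 4,
      px_size = px_size)
    flw <- do.call(flow_spec, sim$flow %||% list(kind = "uniform"))
    seq <- render_sequence(tex, flw, schedule,
                           n_frames = sim$n_frames %||% 10L,
                           dt = sim$dt %||% dt,
                           noise_sd = sim$noise_sd %||% 0,
                           seed = sim$seed, px_size = px_size)
    dt <- attr(seq, "dt_s")
    write_sequence(seq, seq_path)
    write_config(sim$schedule, file.path(out_dir, "schedule.yaml"))
    note("simulate", sim, c(seq_path, file.path(out_dir, "schedule.yaml")))
  }

  needs_seq <- function() {
    if (!file.exists(seq_path) && is.null(config$input_sequence)) {
      abort("stage requires an image sequence: run `simulate` or set `input_sequence`")
    }
    path <- config$input_sequence %||% seq_path
    read_sequence(path, px_size = px_size, dt = dt)
  }
  if (is.null(schedule) && !is.null(config$schedule)) {
    schedule <- config_schedule(config$schedule)
  }

  sp_trace <- NULL
  if (!is.null(config$piv)) {
    pv <- config$piv
    seq <- needs_seq()
    sp_trace <- speed_trace(seq, schedule = schedule,
                            window_px = pv$window %||% 32L,
                            overlap_px = pv$overlap %||% 16L,
                            outlier_threshold = pv$outlier_threshold %||% 2)
    f <- file.path(out_dir, "speed_trace.csv")
    write_trace(sp_trace, f)
    note("piv", pv, f)
  }

  if (!is.null(config$kinetics)) {
    if (is.null(sp_trace)) abort("`kinetics` requires the `piv` stage output")
    if (is.null(schedule)) abort("`kinetics` requires a schedule")
    segs <- segment_cycles(schedule, span = range(sp_trace$time_s))
    fits <- list()
    for (i in which(segs$label == "on")) {
      part <- sp_trace[sp_trace$time_s >= segs$t_start[i] &
                         sp_trace$time_s < segs$t_end[i], ]
      if (nrow(part) >= 5L) {
        ft <- fit_activation(part)
        fits[[length(fits) + 1L]] <-
          cbind(interval = i, tidy(ft))
      }
    }
    f <- file.path(out_dir, "activation_fits.csv")
    write_trace(dplyr::bind_rows(fits), f)
    note("kinetics", config$kinetics, f)
  }

  if (!is.null(config$orient)) {
    orp <- config$orient
    seq <- needs_seq()
    atr <- angle_trace(seq, theta0 = orp$theta0 %||% 0,
                       schedule = schedule,
                       sigma_grad = orp$sigma_grad %||% 1,
                       sigma_window = orp$sigma_window %||% 4,
                       coherence_min = orp$coherence_min %||% 0.3)
    f <- file.path(out_dir, "angle_trace.csv")
    write_trace(atr, f)
    note("orient", orp, f)
  }

  if (!is.null(config$strain)) {
    st <- config$strain
    seq <- needs_seq()
    region <- do.call(rect_region, st$region)
    n <- n_frames(seq)
    fields <- lapply(seq_len(n - 1L), function(k) {
      filter_outliers(piv_pair(get_frame(seq, k), get_frame(seq, k + 1L),
                               window_px = st$window %||% 32L,
                               overlap_px = st$overlap %||% 16L,
                               dt = dt, px_size = px_size))
    })
    disp <- accumulate_displacement(fields, dt = dt)
    strain <- strain_trace(disp, region,
                           erode_um = st$erode_um %||% NULL)
    regime <- classify_regime(strain, eps_x = st$eps_x %||% 0.005,
                              eps_y = st$eps_y %||% 0.005)
    f <- file.path(out_dir, "strain_trace.csv")
    write_trace(strain, f)
    f2 <- file.path(out_dir, "regime.yaml")
    write_config(list(regime = as.character(regime),
                      dgamma_yy = attr(regime, "dgamma_yy"),
                      gamma_xx_final = attr(regime, "gamma_xx_final")), f2)
    note("strain", st, c(f, f2))
  }

  if (!is.null(config$stability)) {
    sb <- config$stability
    data <- if (!is.null(sb$dataset)) {
      read_trace(sb$dataset, "threshold_dataset")
    } else {
      abort("`stability` stage requires `dataset` (threshold CSV path)")
    }
    fit <- fit_activity_coefficient(data)
    gen <- fit_generic_scaling(data)
    f <- file.path(out_dir, "stability_fit.yaml")
    write_config(list(a = unname(fit$params["a"]), a_se = unname(fit$se["a"]),
                      gA = unname(gen$params["gA"]),
                      gC = unname(gen$params["gC"])), f)
    note("stability", sb, f)
  }

  if (length(report$stages) == 0L) abort("config selects no stage")
  class(report) <- "run_report"
  report
}

config_schedule <- function(sched) {
  if (is.null(sched)) abort("a schedule specification is required")
  region <- if (!is.null(sched$region)) do.call(rect_region, sched$region)
  illumination_schedule(t_start = unlist(sched$t_start),
                        t_end = unlist(sched$t_end),
                        intensity = unlist(sched$intensity %||% 1),
                        region = region)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> optoflow", x$version, "\n")
  cat("stages: ", paste(x$stages, collapse = " -> "), "\n")
  cat("files:\n"); for (f in x$files) cat("  ", f, "\n")
  if (length(x$warnings)) {
    cat("warnings:\n"); for (w in x$warnings) cat("  ", w, "\n")
  }
  cat("config hash:", x$config_hash, "\n")
  invisible(x)
}
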