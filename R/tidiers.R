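#' Tidy a fitted optoflow model
#'
#' Returns one row per fitted parameter with its estimate and standard
#' error, in the usual broom layout.
#'
#' @param x An `optoflow_fit` (activation, deactivation, relaxation,
#'   stability or generic-scaling fit).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.optoflow_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = unname(x$params),
                 std.error = unname(x$se[names(x$params)]))
}

#' Glance at a fitted optoflow model
#'
#' @param x An `optoflow_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `rss` (residual sum of squares),
#'   `sigma` (residual standard deviation), `nobs`, and any fit flags
#'   (`degenerate`, `identifiable`).
#' @export
glance.optoflow_fit <- function(x, ...) {
  p <- length(x$params)
  out <- tibble::tibble(rss = x$rss,
                        sigma = sqrt(x$rss / max(x$n - p, 1L)),
                        nobs = x$n)
  if (!is.null(x$degenerate)) out$degenerate <- x$degenerate
  if (!is.null(x$identifiable)) out$identifiable <- x$identifiable
  out
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
print.optoflow_fit <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1L]))
  print(tidy.optoflow_fit(x))
  invisible(x)
}
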