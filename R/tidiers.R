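#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted circuit model
#'
#' @param x An `ios_fit` from [fit_model()].
#' @param ... Unused.
#' @return A tibble with one row per circuit parameter: `term`, `estimate`.
#' @export
tidy.ios_fit <- function(x, ...) {
  tibble::tibble(term = names(x$parameters),
                 estimate = unname(x$parameters))
}

#' One-row summary of a fitted circuit model
#'
#' @param x An `ios_fit` from [fit_model()].
#' @param ... Unused.
#' @return A one-row tibble: `model`, `objective`, `rmse`, `converged`,
#'   `n_starts_used`, `n_frequencies`.
#' @export
glance.ios_fit <- function(x, ...) {
  nres <- 2 * nrow(x$residuals)
  tibble::tibble(model = x$model,
                 objective = x$objective,
                 rmse = sqrt(x$objective / nres),
                 converged = x$converged,
                 n_starts_used = x$n_starts_used,
                 n_frequencies = nrow(x$residuals))
}

#' @export
print.ios_fit <- function(x, ...) {
  cat(sprintf("%s circuit fit (%d starts, converged: %s)\n",
              x$model, x$n_starts_used, x$converged))
  cat("  parameters:\n")
  print(signif(x$parameters, 6))
  cat(sprintf("  objective: %.3e over %d frequencies\n",
              x$objective, nrow(x$residuals)))
  invisible(x)
}

#' @export
print.ios_spectrum <- function(x, ...) {
  cat(sprintf("impedance spectrum, %d frequencies (%g-%g Hz)\n",
              nrow(x), min(x$frequency), max(x$frequency)))
  NextMethod()
}
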