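#' Fitting options for equivalent-circuit estimation
#'
#' Controls the nonlinear least-squares fit of the eRIC or aRIC circuit to a
#' measured spectrum. Fitting uses the 3-25 Hz points only by default: the
#' 35 Hz measurement supports index interpolation but is conventionally
#' excluded from circuit estimation.
#'
#' Bounds are wide boxes around physiological paediatric values:
#' `Rc`, `Rp` in \[1e-3, 5\] kPa·s/L, `I` in \[1e-5, 0.05\] kPa·s²/L,
#' `Cp` in \[1e-3, 2\] L/kPa and `Ce` in \[0, 0.1\] L/kPa. Positive
#' parameters are optimised on the log scale; the shunt compliance `Ce` is
#' optimised on the linear scale so that its no-shunt boundary `Ce = 0` is
#' attainable.
#'
#' @param model `"eric"` or `"aric"`.
#' @param fit_frequencies Frequencies (Hz) used in the objective; must all be
#'   grid points of the spectrum being fitted.
#' @param bounds Named list of `c(lower, upper)` per parameter; defaults as
#'   above.
#' @param n_starts Number of optimisation starts (>= 1). Starts are one
#'   data-driven heuristic plus seeded random draws inside the bounds.
#' @param seed Integer seed making the random starts reproducible.
#' @param tolerance Convergence tolerance passed to the least-squares
#'   backend (relative reduction in the sum of squares).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(model = c("eric", "aric"),
                        fit_frequencies = c(3, 5, 10, 15, 20, 25),
                        bounds = NULL,
                        n_starts = 8L,
                        seed = 1L,
                        tolerance = 1e-14) {
  model <- match.arg(model)
  if (n_starts < 1) abort("n_starts must be >= 1", class = "iosmodel_invalid_input")
  check_frequencies(fit_frequencies)
  bounds <- bounds %||% default_bounds(model)
  need <- param_names(model)
  if (!all(need %in% names(bounds))) {
    abort(paste0("bounds must cover ", paste(need, collapse = ", ")),
          class = "iosmodel_invalid_input")
  }
  for (nm in need) {
    b <- bounds[[nm]]
    lo_ok <- if (nm == "Ce") b[1] >= 0 else b[1] > 0
    if (length(b) != 2 || !lo_ok || b[2] <= b[1]) {
      abort(sprintf("invalid bounds for %s", nm), class = "iosmodel_invalid_input")
    }
  }
  structure(list(model = model,
                 fit_frequencies = sort(as.numeric(fit_frequencies)),
                 bounds = bounds[need],
                 n_starts = as.integer(n_starts),
                 seed = as.integer(seed),
                 tolerance = tolerance),
            class = "fit_options")
}

param_names <- function(model) {
  if (model == "aric") c("Rc", "I", "Rp", "Cp", "Ce") else c("Rc", "I", "Rp", "Cp")
}

default_bounds <- function(model) {
  b <- list(Rc = c(1e-3, 5), I = c(1e-5, 0.05), Rp = c(1e-3, 5), Cp = c(1e-3, 2))
  if (model == "aric") b$Ce <- c(0, 0.1)
  b
}

eval_model <- function(model, params, frequencies) {
  if (model == "aric") eval_aric(params, frequencies)
  else eval_eric(params, frequencies)
}

#' Least-squares objective for a circuit fit
#'
#' The unweighted sum of squared residuals over the fit frequencies,
#' `sum_f (R_model - R_meas)^2 + (X_model - X_meas)^2`. Resistance and
#' reactance share units and magnitude range in IOS data, so the two
#' channels are weighted equally on the absolute scale.
#'
#' @param params Named parameter vector ([eric_params()] or
#'   [aric_params()]).
#' @param spectrum Measured [ios_spectrum()].
#' @param fit_frequencies Frequencies to include; must be grid points of
#'   `spectrum`.
#' @param model `"eric"` or `"aric"`; inferred from the presence of a `Ce`
#'   field when omitted.
#' @return Scalar objective, kPa²·s²/L², >= 0; exactly 0 iff the model
#'   reproduces the measurements at every fit frequency.
#' @export
ios_objective <- function(params, spectrum, fit_frequencies = c(3, 5, 10, 15, 20, 25),
                          model = NULL) {
  model <- model %||% (if ("Ce" %in% names(params)) "aric" else "eric")
  sum(fit_residuals(params, spectrum, fit_frequencies, model)^2)
}

# allocation-free model evaluation used inside optimisation loops; same
# closed forms as eval_eric/eval_aric, asserted equal in the test suite
model_re_im <- function(model, p, w) {
  d <- 1 + (w * p[["Rp"]] * p[["Cp"]])^2
  re <- p[["Rc"]] + p[["Rp"]] / d
  im <- w * p[["I"]] - w * p[["Rp"]]^2 * p[["Cp"]] / d
  if (model == "aric") {
    z <- complex(real = re, imaginary = im)
    z <- z / (1 + 1i * w * p[["Ce"]] * z)
    re <- Re(z); im <- Im(z)
  }
  list(re = re, im = im)
}

# stacked residual vector (delta R then delta X) at the fit frequencies
fit_residuals <- function(params, spectrum, fit_frequencies, model) {
  spectrum <- as_spectrum(spectrum)
  miss <- setdiff(fit_frequencies, spectrum$frequency)
  if (length(miss) > 0) {
    abort(sprintf("spectrum is missing fit frequencies: %s Hz",
                  paste(miss, collapse = ", ")),
          class = "iosmodel_invalid_input")
  }
  keep <- spectrum$frequency %in% fit_frequencies
  meas <- spectrum[keep, ]
  mod <- eval_model(model, params, meas$frequency)
  c(mod$resistance - meas$resistance, mod$reactance - meas$reactance)
}

# map between optimiser space (log for positive params, linear for Ce)
to_opt_space <- function(p, model) {
  th <- log(p[c("Rc", "I", "Rp", "Cp")])
  if (model == "aric") th <- c(th, Ce = unname(p[["Ce"]]))
  th
}
from_opt_space <- function(th, model) {
  p <- exp(th[1:4])
  names(p) <- c("Rc", "I", "Rp", "Cp")
  if (model == "aric") p <- c(p, Ce = unname(th[5]))
  p
}

# data-driven starting point: Rc from the high-frequency resistance plateau,
# Rp from the low/high resistance drop, I from the high-frequency reactance,
# Cp from the 5 Hz reactance (X ~ -1/(w Cp) at low frequency)
heuristic_start <- function(spectrum, opts) {
  ff <- opts$fit_frequencies
  fhi <- max(ff); flo <- min(ff)
  rhi <- value_at(spectrum, fhi, "resistance")
  rlo <- value_at(spectrum, flo, "resistance")
  xhi <- value_at(spectrum, fhi, "reactance")
  f5 <- if (5 >= flo && 5 <= max(spectrum$frequency)) 5 else flo
  x5 <- value_at(spectrum, f5, "reactance")
  b <- opts$bounds
  clamp <- function(x, nm) min(max(x, b[[nm]][1]), b[[nm]][2])
  p <- c(Rc = clamp(rhi, "Rc"),
         I = clamp(if (xhi > 0) xhi / (2 * pi * fhi) else 0.002, "I"),
         Rp = clamp(rlo - rhi, "Rp"),
         Cp = clamp(if (x5 < 0) 1 / (2 * pi * f5 * abs(x5)) else 0.1, "Cp"))
  if (opts$model == "aric") p <- c(p, Ce = 0.001)
  p
}

# seeded random starts uniform in optimiser space, plus the heuristic first
make_starts <- function(spectrum, opts) {
  starts <- list(heuristic_start(spectrum, opts))
  n_rand <- opts$n_starts - 1L
  if (n_rand > 0) {
    nm <- param_names(opts$model)
    lo <- vapply(opts$bounds, `[`, numeric(1), 1)
    hi <- vapply(opts$bounds, `[`, numeric(1), 2)
    th_lo <- to_opt_space(pmax(lo, ifelse(nm == "Ce", 0, lo)), opts$model)
    th_hi <- to_opt_space(hi, opts$model)
    u <- withr_seed(opts$seed, matrix(runif(n_rand * length(nm)), nrow = n_rand))
    for (k in seq_len(n_rand)) {
      th <- th_lo + u[k, ] * (th_hi - th_lo)
      starts[[k + 1L]] <- from_opt_space(th, opts$model)
    }
  }
  starts
}

# run code under a temporary RNG state so fitting never disturbs the
# caller's random stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit an equivalent-circuit model to a measured spectrum
#'
#' Bounded multi-start nonlinear least squares: each start is refined by
#' Levenberg-Marquardt (via [minpack.lm::nls.lm()]) on the stacked
#' resistance/reactance residuals, positive parameters on the log scale,
#' inside the boxes of [fit_options()]; the best converged start wins, ties
#' broken by lowest start index. The result is deterministic given the
#' spectrum and options (including the seed).
#'
#' @param spectrum Measured [ios_spectrum()] (or a data frame with
#'   `frequency`, `resistance`, `reactance` columns) covering all fit
#'   frequencies.
#' @param model `"eric"` or `"aric"`; overridden by `options$model` when
#'   `options` is supplied.
#' @param options A [fit_options()] object.
#' @return An object of class `ios_fit`: a list with elements `parameters`
#'   (named vector), `model`, `objective` (sum of squared residuals),
#'   `residuals` (tibble of per-frequency `delta_r`, `delta_x`),
#'   `converged`, `n_starts_used`, and `options`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' truth <- eric_params(0.3, 0.002, 0.5, 0.1)
#' s <- eval_eric(truth, c(3, 5, 10, 15, 20, 25))
#' fit <- fit_model(s, "eric")
#' tidy(fit)
#' @export
fit_model <- function(spectrum, model = c("eric", "aric"), options = NULL) {
  if (is.null(options)) options <- fit_options(match.arg(model))
  stopifnot(inherits(options, "fit_options"))
  spectrum <- as_spectrum(spectrum)
  miss <- setdiff(options$fit_frequencies, spectrum$frequency)
  if (length(miss) > 0) {
    abort(sprintf("spectrum is missing fit frequencies: %s Hz",
                  paste(miss, collapse = ", ")),
          class = "iosmodel_invalid_input")
  }

  nm <- param_names(options$model)
  lo <- vapply(options$bounds, `[`, numeric(1), 1)
  hi <- vapply(options$bounds, `[`, numeric(1), 2)
  th_lo <- suppressWarnings(to_opt_space(lo, options$model))
  th_hi <- to_opt_space(hi, options$model)
  if (options$model == "aric") th_lo["Ce"] <- 0  # Ce linear, lower bound 0

  keep <- spectrum$frequency %in% options$fit_frequencies
  meas_r <- spectrum$resistance[keep]
  meas_x <- spectrum$reactance[keep]
  w <- 2 * pi * spectrum$frequency[keep]
  resid_fn <- function(th) {
    m <- model_re_im(options$model, from_opt_space(th, options$model), w)
    c(m$re - meas_r, m$im - meas_x)
  }

  starts <- make_starts(spectrum, options)
  best <- NULL
  best_obj <- Inf
  any_converged <- FALSE
  for (k in seq_along(starts)) {
    th0 <- to_opt_space(starts[[k]], options$model)
    th0 <- pmin(pmax(th0, th_lo), th_hi)
    # individual starts may stall at maxiter; that is expected and read off
    # the info code, so the backend's warning is silenced
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = th0, lower = th_lo, upper = th_hi, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             ftol = options$tolerance, ptol = options$tolerance,
                             gtol = 0, maxiter = 500, maxfev = 5000))),
      error = function(e) NULL)
    if (is.null(res)) next
    obj <- res$deviance
    conv <- res$info %in% 1:4
    any_converged <- any_converged || conv
    if (obj < best_obj) {
      best_obj <- obj
      best <- list(theta = res$par, converged = conv, info = res$info, start = k)
    }
  }
  if (is.null(best)) {
    abort("no optimisation start succeeded", class = "iosmodel_nonconvergence")
  }
  if (!any_converged) {
    abort("no optimisation start converged",
          class = "iosmodel_nonconvergence",
          best_parameters = from_opt_space(best$theta, options$model),
          best_objective = best_obj)
  }
  pars <- from_opt_space(best$theta, options$model)
  rv <- fit_residuals(pars, spectrum, options$fit_frequencies, options$model)
  nf <- length(options$fit_frequencies)
  structure(list(
    parameters = pars,
    model = options$model,
    objective = sum(rv^2),
    residuals = tibble::tibble(frequency = options$fit_frequencies,
                               delta_r = rv[seq_len(nf)],
                               delta_x = rv[nf + seq_len(nf)]),
    converged = best$converged,
    n_starts_used = length(starts),
    best_start = best$start,
    spectrum = spectrum,
    options = options
  ), class = "ios_fit")
}

#' Exhaustive coarse grid-search baseline for circuit fitting
#'
#' Evaluates the least-squares objective on a log-spaced lattice inside the
#' fitting bounds (the shunt compliance axis is linearly spaced so 0 is a
#' lattice point) and returns the lattice minimum. This is a brute-force
#' baseline: the local optimiser of [fit_model()] must always reach an
#' objective at least as low.
#'
#' @inheritParams fit_model
#' @param points_per_axis Lattice resolution per parameter (>= 2).
#' @return A list with `parameters`, `objective`, `n_evaluated`.
#' @export
grid_search_oracle <- function(spectrum, model = c("eric", "aric"),
                               points_per_axis = 5, options = NULL) {
  if (is.null(options)) options <- fit_options(match.arg(model))
  if (points_per_axis < 2) {
    abort("points_per_axis must be >= 2", class = "iosmodel_invalid_input")
  }
  spectrum <- as_spectrum(spectrum)
  nm <- param_names(options$model)
  axes <- lapply(nm, function(p) {
    b <- options$bounds[[p]]
    if (p == "Ce") seq(b[1], b[2], length.out = points_per_axis)
    else exp(seq(log(b[1]), log(b[2]), length.out = points_per_axis))
  })
  names(axes) <- nm
  lattice <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  keep <- spectrum$frequency %in% options$fit_frequencies
  miss <- setdiff(options$fit_frequencies, spectrum$frequency)
  if (length(miss) > 0) {
    abort(sprintf("spectrum is missing fit frequencies: %s Hz",
                  paste(miss, collapse = ", ")),
          class = "iosmodel_invalid_input")
  }
  meas_r <- spectrum$resistance[keep]
  meas_x <- spectrum$reactance[keep]
  w <- 2 * pi * spectrum$frequency[keep]
  objs <- apply(lattice, 1, function(row) {
    m <- model_re_im(options$model, setNames(row, nm), w)
    sum((m$re - meas_r)^2 + (m$im - meas_x)^2)
  })
  i <- which.min(objs)
  list(parameters = setNames(lattice[i, ], nm),
       objective = objs[i],
       n_evaluated = nrow(lattice))
}
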