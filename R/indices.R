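#' Interpolate a spectrum channel at an arbitrary frequency
#'
#' Returns the exact grid value when `f` is a grid point and linear
#' interpolation between the bracketing grid points otherwise. Extrapolation
#' beyond the grid span is refused: the standard IOS indices are defined
#' only inside the measured 3-35 Hz range.
#'
#' @param spectrum An [ios_spectrum()] (any data frame with `frequency` and
#'   the requested channel column is accepted).
#' @param f Query frequency (Hz); may be a vector.
#' @param channel `"resistance"` or `"reactance"`.
#' @return Numeric vector of interpolated values, kPa·s/L.
#' @examples
#' s <- ios_spectrum(c(10, 20), c(0.5, 0.3), c(-0.1, 0.05))
#' value_at(s, 15, "resistance")  # 0.4
#' @export
value_at <- function(spectrum, f, channel = c("resistance", "reactance")) {
  channel <- match.arg(channel)
  spectrum <- as_spectrum(spectrum)
  grid <- spectrum$frequency
  if (any(f < min(grid)) || any(f > max(grid))) {
    abort(sprintf("frequency %s Hz outside grid span [%g, %g]; no extrapolation",
                  paste(f[f < min(grid) | f > max(grid)], collapse = ", "),
                  min(grid), max(grid)),
          class = "iosmodel_out_of_range")
  }
  stats::approx(grid, spectrum[[channel]], xout = f, method = "linear",
                ties = "ordered")$y
}

# coerce/validate a data frame into a canonical spectrum
as_spectrum <- function(x) {
  if (inherits(x, "ios_spectrum")) return(x)
  if (!is.data.frame(x) || !all(c("frequency", "resistance", "reactance") %in% names(x))) {
    abort("expected a spectrum with columns frequency, resistance, reactance",
          class = "iosmodel_invalid_input")
  }
  ios_spectrum(x$frequency, x$resistance, x$reactance)
}

#' Frequency dependence of resistance (fdR = R5 - R20)
#'
#' Resistance that falls with oscillation frequency marks peripheral
#' (small-airway) obstruction; the drop between 5 and 20 Hz is the standard
#' scalar index of that frequency dependence.
#'
#' @inheritParams value_at
#' @return fdR in kPa·s/L.
#' @export
compute_fdr <- function(spectrum) {
  value_at(spectrum, 5, "resistance") - value_at(spectrum, 20, "resistance")
}

#' Resonant frequency of a measured spectrum
#'
#' The resonant frequency Fres is the point at which reactance crosses zero.
#' The first (lowest-frequency) negative-to-non-negative crossing is
#' returned, linearly interpolated between the bracketing grid points; an
#' exact zero at a grid point returns that frequency. When the reactance is
#' negative over the whole grid, or already non-negative at the lowest
#' frequency, no crossing exists and `NA_real_` is returned.
#'
#' @inheritParams value_at
#' @return Fres in Hz, or `NA_real_`.
#' @export
compute_fres <- function(spectrum) {
  spectrum <- as_spectrum(spectrum)
  f <- spectrum$frequency
  x <- spectrum$reactance
  if (x[1] >= 0) return(NA_real_)
  for (i in seq_len(length(f) - 1)) {
    if (x[i] < 0 && x[i + 1] >= 0) {
      if (x[i + 1] == 0) return(f[i + 1])
      return(f[i] + (f[i + 1] - f[i]) * (-x[i]) / (x[i + 1] - x[i]))
    }
  }
  NA_real_
}

#' Reactance area (AX, the "Goldman triangle")
#'
#' The integrated magnitude of the (negative) low-frequency reactance from
#' 5 Hz up to the resonant frequency, by the trapezoidal rule over the grid
#' points between the interpolated 5 Hz endpoint and the zero crossing. AX
#' is an integrative index of small-airway function: peripheral obstruction
#' makes low-frequency reactance more negative and pushes the zero crossing
#' up, both of which enlarge the area.
#'
#' Conventions: when the reactance at 5 Hz is already non-negative the area
#' is 0; when no zero crossing exists below the top of the grid the area is
#' undefined and `NA_real_` is returned (flagged, never silently zero).
#'
#' @inheritParams value_at
#' @return AX in kPa/L, 0, or `NA_real_` when Fres is undefined.
#' @export
compute_ax <- function(spectrum) {
  spectrum <- as_spectrum(spectrum)
  x5 <- value_at(spectrum, 5, "reactance")
  if (x5 >= 0) return(0)
  fres <- compute_fres(spectrum)
  if (is.na(fres)) return(NA_real_)
  if (fres <= 5) return(0)
  inner <- spectrum$frequency[spectrum$frequency > 5 & spectrum$frequency < fres]
  knots <- c(5, inner, fres)
  vals <- abs(c(x5, value_at(spectrum, inner, "reactance"), 0))
  sum(diff(knots) * (head(vals, -1) + vals[-1]) / 2)
}

#' Compute the hallmark IOS indices of a spectrum
#'
#' Bundles the per-spectrum indices into a one-row tibble: resistance at
#' 5 and 20 Hz (`r5`, `r20`), their difference (`fdr`), reactance at 5 Hz
#' (`x5`), the resonant frequency (`fres`, NA when the reactance never
#' crosses zero) and the reactance area (`ax`, NA when undefined).
#'
#' @inheritParams value_at
#' @return A one-row tibble with columns `r5`, `r20`, `fdr`, `x5`, `fres`,
#'   `ax`.
#' @examples
#' s <- eval_eric(eric_params(0.3, 0.002, 0.8, 0.05), c(3, 5, 10, 15, 20, 25, 35))
#' compute_indices(s)
#' @export
compute_indices <- function(spectrum) {
  spectrum <- as_spectrum(spectrum)
  r5 <- value_at(spectrum, 5, "resistance")
  r20 <- value_at(spectrum, 20, "resistance")
  tibble::tibble(
    r5 = r5,
    r20 = r20,
    fdr = r5 - r20,
    x5 = value_at(spectrum, 5, "reactance"),
    fres = compute_fres(spectrum),
    ax = compute_ax(spectrum)
  )
}
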