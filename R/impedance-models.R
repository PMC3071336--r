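#' Equivalent-circuit parameter sets
#'
#' Constructors for the two lumped-parameter respiratory circuit models used
#' throughout the package. The extended RIC (eRIC) circuit places a central
#' (large-airway) resistance `Rc` in series with an airway inertance `I` and a
#' peripheral branch consisting of the small-airway resistance `Rp` in
#' parallel with the small-airway compliance `Cp`. The augmented RIC (aRIC)
#' circuit adds an extrathoracic shunt compliance `Ce` in parallel across the
#' whole eRIC branch; it captures the rise in measured resistance at high
#' oscillation frequencies caused by upper-airway (cheek/pharynx) shunting.
#'
#' Units follow forced-oscillation convention: resistances in kPa·s/L,
#' inertance in kPa·s²/L, compliances in L/kPa.
#'
#' @param Rc Central (large-airway) resistance, kPa·s/L. Must be > 0.
#' @param I Large-airway inertance, kPa·s²/L. Must be > 0.
#' @param Rp Peripheral (small-airway) resistance, kPa·s/L. Must be >= 0;
#'   `Rp = 0` is accepted as a degenerate open-branch limit for evaluation
#'   (the fitting bounds exclude it).
#' @param Cp Peripheral (small-airway) compliance, L/kPa. Must be >= 0;
#'   `Cp = 0` is the degenerate limit in which the peripheral branch reduces
#'   to `Rp`.
#' @param Ce Extrathoracic shunt compliance, L/kPa. Must be >= 0; `Ce = 0`
#'   reproduces the eRIC model exactly.
#' @return A named numeric vector of class `eric_params` or `aric_params`.
#' @examples
#' eric_params(Rc = 0.3, I = 0.002, Rp = 0.5, Cp = 0.1)
#' aric_params(Rc = 0.3, I = 0.002, Rp = 0.5, Cp = 0.1, Ce = 0.005)
#' @export
eric_params <- function(Rc, I, Rp, Cp) {
  p <- c(Rc = as.numeric(Rc), I = as.numeric(I),
         Rp = as.numeric(Rp), Cp = as.numeric(Cp))
  validate_params(p, model = "eric")
  structure(p, class = "eric_params")
}

#' @rdname eric_params
#' @export
aric_params <- function(Rc, I, Rp, Cp, Ce) {
  p <- c(Rc = as.numeric(Rc), I = as.numeric(I),
         Rp = as.numeric(Rp), Cp = as.numeric(Cp), Ce = as.numeric(Ce))
  validate_params(p, model = "aric")
  structure(p, class = "aric_params")
}

validate_params <- function(p, model = c("eric", "aric")) {
  model <- match.arg(model)
  need <- if (model == "eric") c("Rc", "I", "Rp", "Cp")
          else c("Rc", "I", "Rp", "Cp", "Ce")
  if (!all(need %in% names(p))) {
    abort(paste0("parameters must be named ", paste(need, collapse = ", ")),
          class = "iosmodel_invalid_input")
  }
  p <- p[need]
  if (anyNA(p) || !all(is.finite(p))) {
    abort("parameters must be finite and non-missing",
          class = "iosmodel_invalid_input")
  }
  if (p[["Rc"]] <= 0 || p[["I"]] <= 0) {
    abort("Rc and I must be strictly positive",
          class = "iosmodel_invalid_input")
  }
  # Rp = 0 / Cp = 0 are tolerated as degenerate evaluation limits
  if (p[["Rp"]] < 0 || p[["Cp"]] < 0) {
    abort("Rp and Cp must be non-negative",
          class = "iosmodel_invalid_input")
  }
  if (model == "aric" && p[["Ce"]] < 0) {
    abort("Ce must be non-negative", class = "iosmodel_invalid_input")
  }
  invisible(p)
}

check_frequencies <- function(frequencies) {
  if (length(frequencies) == 0 || anyNA(frequencies) ||
      !all(is.finite(frequencies)) || any(frequencies <= 0)) {
    abort("frequencies must be finite and strictly positive",
          class = "iosmodel_invalid_input")
  }
  invisible(as.numeric(frequencies))
}

#' Construct an impedance spectrum
#'
#' An impedance spectrum is a tibble with one row per oscillation frequency
#' holding the real part (`resistance`) and imaginary part (`reactance`) of
#' the complex respiratory input impedance, both in kPa·s/L. Rows are sorted
#' canonically by frequency; duplicate or non-positive frequencies and
#' non-positive resistances are rejected.
#'
#' @param frequency Oscillation frequencies, Hz.
#' @param resistance Real part of impedance at each frequency, kPa·s/L.
#' @param reactance Imaginary part of impedance at each frequency, kPa·s/L.
#' @return A tibble of class `ios_spectrum` with columns `frequency`,
#'   `resistance`, `reactance`, sorted by increasing frequency.
#' @examples
#' ios_spectrum(c(5, 20), c(0.5, 0.3), c(-0.2, 0.05))
#' @export
ios_spectrum <- function(frequency, resistance, reactance) {
  if (length(frequency) != length(resistance) ||
      length(frequency) != length(reactance)) {
    abort("frequency, resistance and reactance must have equal length",
          class = "iosmodel_invalid_input")
  }
  check_frequencies(frequency)
  if (anyNA(resistance) || anyNA(reactance) ||
      !all(is.finite(resistance)) || !all(is.finite(reactance))) {
    abort("resistance and reactance must be finite", class = "iosmodel_invalid_input")
  }
  if (any(resistance <= 0)) {
    abort("resistance must be strictly positive",
          class = "iosmodel_invalid_input")
  }
  ord <- order(frequency)
  frequency <- as.numeric(frequency[ord])
  if (anyDuplicated(frequency)) {
    abort("duplicate frequencies in spectrum", class = "iosmodel_invalid_input")
  }
  out <- tibble::tibble(
    frequency = frequency,
    resistance = as.numeric(resistance[ord]),
    reactance = as.numeric(reactance[ord])
  )
  class(out) <- c("ios_spectrum", class(out))
  out
}

#' Evaluate the eRIC circuit impedance
#'
#' Computes the complex input impedance of the extended RIC circuit,
#' `Z(w) = Rc + jwI + Rp / (1 + jw Rp Cp)` with `w = 2*pi*f`, and returns its
#' real and imaginary parts as an impedance spectrum. The real part decreases
#' strictly with frequency (from `Rc + Rp` at DC towards `Rc` at high
#' frequency), the classic signature of peripheral (small-airway)
#' obstruction; the imaginary part runs from compliance-dominated (negative)
#' at low frequency to inertance-dominated (positive) at high frequency.
#'
#' @param params An [eric_params()] set (or any named vector with fields
#'   `Rc`, `I`, `Rp`, `Cp`).
#' @param frequencies Oscillation frequencies, Hz, all > 0.
#' @return An [ios_spectrum()] on the given grid.
#' @examples
#' eval_eric(eric_params(0.3, 0.002, 0.5, 0.1), c(3, 5, 10, 15, 20, 25))
#' @export
eval_eric <- function(params, frequencies) {
  p <- validate_params(params, "eric")
  f <- check_frequencies(frequencies)
  w <- 2 * pi * f
  d <- 1 + (w * p[["Rp"]] * p[["Cp"]])^2
  re <- p[["Rc"]] + p[["Rp"]] / d
  im <- w * p[["I"]] - w * p[["Rp"]]^2 * p[["Cp"]] / d
  ios_spectrum(f, re, im)
}

#' Evaluate the aRIC circuit impedance
#'
#' The augmented RIC circuit places the shunt compliance `Ce` in parallel
#' across the whole eRIC branch, so
#' `Z_aRIC(w) = Z_eRIC(w) / (1 + jw Ce Z_eRIC(w))`. With `Ce = 0` the output
#' equals [eval_eric()] at every frequency.
#'
#' @param params An [aric_params()] set (fields `Rc`, `I`, `Rp`, `Cp`, `Ce`).
#' @inheritParams eval_eric
#' @return An [ios_spectrum()] on the given grid.
#' @examples
#' eval_aric(aric_params(0.3, 0.002, 0.5, 0.1, 0.005), c(5, 25))
#' @export
eval_aric <- function(params, frequencies) {
  p <- validate_params(params, "aric")
  f <- check_frequencies(frequencies)
  ze <- eval_eric(p[c("Rc", "I", "Rp", "Cp")], f)
  z <- complex(real = ze$resistance, imaginary = ze$reactance)
  w <- 2 * pi * f
  za <- z / (1 + 1i * w * p[["Ce"]] * z)
  ios_spectrum(f, Re(za), Im(za))
}

#' Closed-form resonant frequency of the eRIC circuit
#'
#' Solves `Im Z(w) = 0` for the eRIC model. The reactance crosses zero at
#' `w^2 = (Rp^2 Cp - I) / (I Rp^2 Cp^2)`, which has a positive solution only
#' when `Rp^2 Cp > I`; otherwise the model reactance is non-negative
#' everywhere and no resonant frequency exists.
#'
#' @inheritParams eval_eric
#' @return The resonant frequency in Hz, or `NA_real_` when the circuit has
#'   no zero crossing.
#' @examples
#' model_fres(eric_params(0.3, 0.002, 0.5, 0.1))  # ~3.41 Hz
#' @export
model_fres <- function(params) {
  p <- validate_params(params, "eric")
  num <- p[["Rp"]]^2 * p[["Cp"]] - p[["I"]]
  if (num <= 0) return(NA_real_)
  w2 <- num / (p[["I"]] * p[["Rp"]]^2 * p[["Cp"]]^2)
  sqrt(w2) / (2 * pi)
}
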