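#' Group archetypes for synthetic cohort generation
#'
#' An archetype holds, for one clinical group, the mean eRIC parameters, the
#' between-subject log-normal coefficient of variation per parameter, and
#' the multiplicative "growth" (first to second visit, pre-bronchodilator)
#' and "bronchodilator" (pre to post, second visit) effects.
#'
#' The defaults emulate a two-group paediatric study: a healthy group
#' (`"H"`, higher peripheral compliance) and a small-airway-impaired group
#' (`"SAI"`, higher peripheral resistance, lower compliance). Mean `Rp`/`Cp`
#' and their effect multipliers are set from published group means and
#' percent changes for such cohorts; `Rc` and `I` means and all dispersion
#' values are calibration choices producing realistic child spectra
#' (R5 about 0.5-0.7 kPa·s/L, resonant frequency about 15-22 Hz).
#'
#' @param group Group label, `"H"` or `"SAI"`.
#' @param means Named vector of mean eRIC parameters (`Rc`, `I`, `Rp`, `Cp`).
#' @param cv Named vector (same names) of log-normal coefficients of
#'   variation; 0 switches between-subject spread off.
#' @param growth,bronchodilator Named vectors of strictly positive
#'   multipliers applied to the latent parameters for the growth and
#'   bronchodilator effects.
#' @return A list of class `group_archetype`.
#' @export
group_archetype <- function(group, means, cv, growth, bronchodilator) {
  nm <- c("Rc", "I", "Rp", "Cp")
  for (v in list(means, cv, growth, bronchodilator)) {
    if (!all(nm %in% names(v))) {
      abort("archetype vectors must be named Rc, I, Rp, Cp",
            class = "iosmodel_invalid_input")
    }
  }
  if (any(means[nm] <= 0)) abort("archetype means must be positive",
                                 class = "iosmodel_invalid_input")
  if (any(cv[nm] < 0)) abort("cv must be non-negative",
                             class = "iosmodel_invalid_input")
  if (any(growth[nm] <= 0) || any(bronchodilator[nm] <= 0)) {
    abort("effect multipliers must be strictly positive",
          class = "iosmodel_invalid_input")
  }
  structure(list(group = group, means = means[nm], cv = cv[nm],
                 growth = growth[nm], bronchodilator = bronchodilator[nm]),
            class = "group_archetype")
}

#' @rdname group_archetype
#' @param cv_all Single coefficient of variation applied to every parameter
#'   in the default archetypes.
#' @export
default_archetypes <- function(cv_all = 0.25) {
  cv <- c(Rc = cv_all, I = cv_all, Rp = cv_all, Cp = cv_all)
  list(
    H = group_archetype(
      "H",
      means = c(Rc = 0.35, I = 0.0020, Rp = 0.501, Cp = 0.115),
      cv = cv,
      growth = c(Rc = 0.92, I = 1.00, Rp = 0.94, Cp = 1.35),
      bronchodilator = c(Rc = 0.95, I = 1.00, Rp = 0.82, Cp = 1.12)),
    SAI = group_archetype(
      "SAI",
      means = c(Rc = 0.40, I = 0.0018, Rp = 0.824, Cp = 0.045),
      cv = cv,
      growth = c(Rc = 0.92, I = 1.00, Rp = 0.73, Cp = 1.25),
      bronchodilator = c(Rc = 0.95, I = 1.00, Rp = 0.79, Cp = 1.35))
  )
}

#' Synthetic cohort configuration
#'
#' Defines the shape of a generated study: group sizes (default 7 healthy
#' and 19 small-airway-impaired children), the measurement frequency grid,
#' additive measurement noise on resistance and reactance, between-subject
#' spread, and the master seed.
#'
#' @param n_h,n_sai Number of subjects per group (>= 1).
#' @param grid Measurement frequency grid, Hz.
#' @param noise_sd_r,noise_sd_x Additive Gaussian noise standard deviation
#'   on resistance and reactance, kPa·s/L (>= 0).
#' @param cv Between-subject log-normal coefficient of variation used for
#'   the default archetypes.
#' @param seed Master seed; expanded into per-subject, per-record
#'   substreams by stable hashing so that results are reproducible and
#'   insensitive to cohort-size changes.
#' @param archetypes List of [group_archetype()]s named by group label.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_h = 7L, n_sai = 19L,
                          grid = c(3, 5, 10, 15, 20, 25, 35),
                          noise_sd_r = 0.01, noise_sd_x = 0.01,
                          cv = 0.25, seed = 1L,
                          archetypes = default_archetypes(cv)) {
  if (n_h < 1 || n_sai < 1) abort("group sizes must be >= 1",
                                  class = "iosmodel_invalid_input")
  if (noise_sd_r < 0 || noise_sd_x < 0) abort("noise sd must be >= 0",
                                              class = "iosmodel_invalid_input")
  check_frequencies(grid)
  if (!all(c("H", "SAI") %in% names(archetypes))) {
    abort("archetypes must contain H and SAI", class = "iosmodel_invalid_input")
  }
  structure(list(n_h = as.integer(n_h), n_sai = as.integer(n_sai),
                 grid = sort(as.numeric(grid)),
                 noise_sd_r = noise_sd_r, noise_sd_x = noise_sd_x,
                 seed = as.integer(seed), archetypes = archetypes),
            class = "cohort_config")
}

# stable 31-bit hash of a string, combined with the master seed; keeps every
# derived seed a valid 32-bit integer
substream_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + as.numeric(seed) * 48271) %% 2147483647)
}

#' Draw one subject's latent circuit parameters
#'
#' Each parameter is drawn log-normal with the archetype mean as the
#' distribution (arithmetic) mean and the archetype coefficient of
#' variation: `sdlog^2 = log(1 + cv^2)`, `meanlog = log(mean) - sdlog^2/2`.
#' With `cv = 0` the draw is exactly the archetype mean.
#'
#' @param config A [cohort_config()].
#' @param group `"H"` or `"SAI"`.
#' @param seed Integer seed for this draw (derive via the config master seed
#'   for cohort generation).
#' @return Named latent eRIC parameter vector.
#' @export
sample_subject <- function(config, group, seed) {
  arch <- config$archetypes[[group]]
  if (is.null(arch)) abort(sprintf("no archetype for group '%s'", group),
                           class = "iosmodel_invalid_input")
  withr_seed(seed, {
    sdlog <- sqrt(log(1 + arch$cv^2))
    meanlog <- log(arch$means) - sdlog^2 / 2
    setNames(exp(rnorm(4, meanlog, sdlog)), names(arch$means))
  })
}

#' Apply a growth or bronchodilator effect to latent parameters
#'
#' Elementwise multiplication of the latent eRIC parameters by the
#' archetype's effect multipliers (growth: airway calibre increases, so
#' peripheral resistance falls and compliance rises; bronchodilation:
#' smooth-muscle relaxation with the same directions over a shorter time
#' scale).
#'
#' @param latent Named latent eRIC parameter vector.
#' @param effect `"growth"` or `"bronchodilator"`.
#' @param archetype A [group_archetype()].
#' @return The modified latent parameter vector.
#' @export
apply_effect <- function(latent, effect = c("growth", "bronchodilator"),
                         archetype) {
  effect <- match.arg(effect)
  mult <- archetype[[effect]]
  if (any(mult <= 0)) abort("effect multipliers must be positive",
                            class = "iosmodel_invalid_input")
  latent[names(mult)] * mult
}

#' Simulate one measured spectrum from latent parameters
#'
#' Evaluates the eRIC model on the grid and adds independent Gaussian
#' measurement noise per channel. Negative noisy resistances are physically
#' impossible, so the resistance vector is redrawn (up to 100 attempts)
#' whenever any entry is <= 0; exhausting the redraws raises a
#' degenerate-noise error.
#'
#' @param latent Named latent eRIC parameter vector.
#' @param grid Frequency grid, Hz.
#' @param noise_sd_r,noise_sd_x Noise standard deviations, kPa·s/L.
#' @param seed Integer seed for this record's noise.
#' @return An [ios_spectrum()].
#' @export
synthesize_visit <- function(latent, grid, noise_sd_r, noise_sd_x, seed) {
  clean <- eval_eric(latent, grid)
  withr_seed(seed, {
    n <- length(grid)
    r <- clean$resistance + rnorm(n, 0, noise_sd_r)
    attempts <- 0
    while (any(r <= 0)) {
      attempts <- attempts + 1
      if (attempts >= 100) {
        abort("noise repeatedly produced non-positive resistance",
              class = "iosmodel_degenerate_noise")
      }
      r <- clean$resistance + rnorm(n, 0, noise_sd_r)
    }
    x <- clean$reactance + rnorm(n, 0, noise_sd_x)
    ios_spectrum(clean$frequency, r, x)
  })
}

#' Generate a synthetic longitudinal bronchodilator cohort
#'
#' Builds the full study structure: for every subject a latent eRIC
#' parameter set is drawn for the first visit (pre-bronchodilator only —
#' no bronchodilator was given at the first visit), the growth effect gives
#' the second-visit pre-bronchodilator latent state, and the bronchodilator
#' effect applied on top gives the second-visit post-bronchodilator state.
#' One noisy spectrum is synthesised per record. Everything is reproducible
#' from the config's master seed.
#'
#' @param config A [cohort_config()].
#' @return A tibble of class `ios_cohort` with one row per record and
#'   columns `subject_id`, `group`, `visit` (`"2006"`/`"2008"`), `condition`
#'   (`"preB"`/`"postB"`), `latent` (list of named parameter vectors) and
#'   `spectrum` (list of [ios_spectrum()]s).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_h = 2, n_sai = 2, seed = 42))
#' nrow(cohort)  # 4 subjects x 3 visit-conditions
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- tibble::tibble(
    subject_id = c(sprintf("H%02d", seq_len(config$n_h)),
                   sprintf("S%02d", seq_len(config$n_sai))),
    group = c(rep("H", config$n_h), rep("SAI", config$n_sai))
  )
  records <- purrr::pmap_dfr(subjects, function(subject_id, group) {
    arch <- config$archetypes[[group]]
    base <- sample_subject(config, group,
                           substream_seed(config$seed, subject_id, "latent"))
    grown <- apply_effect(base, "growth", arch)
    dilated <- apply_effect(grown, "bronchodilator", arch)
    tibble::tibble(
      subject_id = subject_id, group = group,
      visit = c("2006", "2008", "2008"),
      condition = c("preB", "preB", "postB"),
      latent = list(base, grown, dilated)
    )
  })
  records$spectrum <- purrr::pmap(
    records[c("subject_id", "visit", "condition", "latent")],
    function(subject_id, visit, condition, latent) {
      synthesize_visit(latent, config$grid, config$noise_sd_r, config$noise_sd_x,
                       substream_seed(config$seed, subject_id, visit, condition))
    })
  class(records) <- c("ios_cohort", class(records))
  records
}
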