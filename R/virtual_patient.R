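#' Construct a virtual patient
#'
#' A virtual patient bundles a ground-truth rigidity–frequency curve, a
#' measurement-noise level, a tolerability ceiling, and a latent value
#' function driving probit preference choices. The rigidity curve is the
#' minimal smooth family reproducing the qualitative features reported for
#' akinetic-rigid patients: a local dip near 10 Hz, worsening at 20–50 Hz,
#' a steep logistic benefit above ~60–80 Hz and an optional non-monotonic
#' bump in the 130–155 Hz band:
#'
#' `r(f) = r_off - dip10_amp * g(f; dip10_center, dip10_width)
#'        + worsen_amp * g(f; worsen_center, worsen_width)
#'        - benefit_amp * logistic((f - benefit_center) / benefit_slope)
#'        + bump_amp * g(f; bump_center, bump_width)`
#'
#' with `g` an unnormalized Gaussian. The value function combines the
#' normalized rigidity benefit with a softplus side-effect penalty rising
#' above `se_onset`, so its peak sits below the rigidity optimum.
#'
#' @param profile `"ar1"` (ceiling 155 Hz, monotone high-frequency benefit)
#'   or `"ar2"` (ceiling 185 Hz, 130–155 Hz bump); `"custom"` uses only the
#'   overrides.
#' @param rng_seed integer seed attached to the patient (used when callers
#'   do not pass their own).
#' @param ... overrides for any field of `rigidity_curve` (`r_off`,
#'   `dip10_amp`, `dip10_center`, `dip10_width`, `worsen_amp`,
#'   `worsen_center`, `worsen_width`, `benefit_amp`, `benefit_center`,
#'   `benefit_slope`, `bump_amp`, `bump_center`, `bump_width`), plus
#'   `noise_sd`, `ceiling`, `lambda_se`, `se_onset`, `se_slope`,
#'   `pref_noise`.
#' @return an object of class `virtual_patient`.
#' @export
virtual_patient <- function(profile = c("ar1", "ar2", "custom"),
                            rng_seed = 1, ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    ar1 = list(
      r_off = 2.0, dip10_amp = 0.25, dip10_center = 10, dip10_width = 8,
      worsen_amp = 0.20, worsen_center = 35, worsen_width = 12,
      benefit_amp = 1.2, benefit_center = 90, benefit_slope = 18,
      bump_amp = 0, bump_center = 140, bump_width = 10,
      noise_sd = NA_real_, ceiling = 155,
      lambda_se = 0.30, se_onset = 118, se_slope = 10, pref_noise = 0.1),
    ar2 = list(
      r_off = 2.4, dip10_amp = 0.30, dip10_center = 10, dip10_width = 8,
      worsen_amp = 0.25, worsen_center = 35, worsen_width = 12,
      benefit_amp = 1.5, benefit_center = 90, benefit_slope = 18,
      bump_amp = 0.25, bump_center = 140, bump_width = 10,
      noise_sd = NA_real_, ceiling = 185,
      lambda_se = 0.30, se_onset = 123, se_slope = 10, pref_noise = 0.1),
    custom = list(
      r_off = 2.0, dip10_amp = 0, dip10_center = 10, dip10_width = 8,
      worsen_amp = 0, worsen_center = 35, worsen_width = 12,
      benefit_amp = 1.0, benefit_center = 85, benefit_slope = 12,
      bump_amp = 0, bump_center = 140, bump_width = 10,
      noise_sd = NA_real_, ceiling = 185,
      lambda_se = 0.30, se_onset = 105, se_slope = 10, pref_noise = 0.1))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown))
    invalid_parameter(sprintf("unknown virtual_patient field(s): %s",
                              paste(unknown, collapse = ", ")))
  base[names(dots)] <- dots

  curve_fields <- c("r_off", "dip10_amp", "dip10_center", "dip10_width",
                    "worsen_amp", "worsen_center", "worsen_width",
                    "benefit_amp", "benefit_center", "benefit_slope",
                    "bump_amp", "bump_center", "bump_width")
  p <- structure(list(
    profile = profile,
    rigidity_curve = base[curve_fields],
    noise_sd = base$noise_sd,
    ceiling = base$ceiling,
    value_fn = list(lambda_se = base$lambda_se, se_onset = base$se_onset,
                    se_slope = base$se_slope, pref_noise = base$pref_noise),
    rng_seed = as.integer(rng_seed)
  ), class = "virtual_patient")

  grid <- seq(10, 185, by = 1)
  r <- true_rigidity(p, grid)
  if (any(r <= 0))
    invalid_parameter("rigidity curve must stay positive on [10, 185] Hz")
  if (p$rigidity_curve$benefit_amp >= p$rigidity_curve$r_off)
    invalid_parameter("benefit_amp must be below r_off")
  # default measurement noise: 5% of the curve's dynamic range
  if (is.na(p$noise_sd)) p$noise_sd <- 0.05 * (max(r) - min(r))
  v <- patient_value(p, grid)
  if (sum(v >= max(v) - 1e-12) != 1L)
    invalid_parameter("value function must have a unique argmax on the grid")
  p
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf(
    "<virtual_patient '%s'> ceiling %g Hz, noise_sd %.3g, pref_noise %.3g\n",
    x$profile, x$ceiling, x$noise_sd, x$value_fn$pref_noise))
  invisible(x)
}

gauss_bump <- function(f, center, width) exp(-(f - center)^2 / (2 * width^2))
logistic <- function(z) 1 / (1 + exp(-z))
softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

#' Ground-truth rigidity of a virtual patient
#'
#' Deterministic rigidity–frequency curve (in RoMaR units) used to generate
#' measurements; see [virtual_patient()] for the functional form.
#'
#' @param patient a [virtual_patient()].
#' @param f stimulation frequency (Hz), vectorized, within `[10, 185]`.
#' @return RoMaR value(s).
#' @export
true_rigidity <- function(patient, f) {
  stopifnot(inherits(patient, "virtual_patient"))
  if (any(f < 10 - 1e-9 | f > 185 + 1e-9))
    invalid_parameter("frequency must lie within [10, 185] Hz")
  cv <- patient$rigidity_curve
  cv$r_off -
    cv$dip10_amp * gauss_bump(f, cv$dip10_center, cv$dip10_width) +
    cv$worsen_amp * gauss_bump(f, cv$worsen_center, cv$worsen_width) -
    cv$benefit_amp * logistic((f - cv$benefit_center) / cv$benefit_slope) +
    cv$bump_amp * gauss_bump(f, cv$bump_center, cv$bump_width)
}

#' Latent preference value of a virtual patient
#'
#' `v(f) = normalized_benefit(f) - lambda_se * softplus((f - se_onset) / se_slope)`
#' where `normalized_benefit(f) = (r_off - true_rigidity(f)) / benefit_amp`.
#' The side-effect penalty makes the argmax of `v` sit near the lowest
#' frequency achieving ~80% of the maximal rigidity benefit, below the
#' rigidity argmin.
#'
#' @inheritParams true_rigidity
#' @return value(s), dimensionless.
#' @export
patient_value <- function(patient, f) {
  stopifnot(inherits(patient, "virtual_patient"))
  cv <- patient$rigidity_curve
  vf <- patient$value_fn
  nb <- (cv$r_off - true_rigidity(patient, f)) / cv$benefit_amp
  nb - vf$lambda_se * softplus((f - vf$se_onset) / vf$se_slope)
}

#' Simulate one noisy RoMaR measurement
#'
#' Draws `true_rigidity(f) + N(0, noise_sd^2)`, floored at zero. Testing a
#' frequency above the patient's tolerability ceiling does not produce a
#' measurement: it signals a `dbstune_intolerable` condition for the session
#' loop to catch.
#'
#' @inheritParams true_rigidity
#' @param f a single frequency in Hz.
#' @param seed integer seed for the noise draw (defaults to the patient's).
#' @return a RoMaR value.
#' @export
measure_romar <- function(patient, f, seed = patient$rng_seed) {
  stopifnot(inherits(patient, "virtual_patient"), length(f) == 1L)
  if (f > patient$ceiling) intolerable_frequency(f)
  y <- true_rigidity(patient, f) +
    with_seed(seed, stats::rnorm(1, 0, patient$noise_sd))
  max(y, 0)
}

#' Simulate a raw torque trace for one trial
#'
#' Generates the torque a manipulandum would record while imposing a
#' sinusoidal passive movement of `rom_deg` amplitude at `move_hz`:
#' `torque(t) = stiffness * theta(t) + viscous * theta'(t) + noise`. The
#' stiffness is calibrated (given the viscous fraction) so that
#' [compute_romar()] of the trace reproduces `true_rigidity(patient, f)`
#' within a few percent in expectation, using the closed form
#' `RoMaR = 2A/pi` for a sinusoid of torque amplitude `A`.
#'
#' @inheritParams measure_romar
#' @param fs sampling rate Hz.
#' @param duration trial length in seconds.
#' @param rom_deg movement amplitude in degrees.
#' @param move_hz imposed movement frequency in Hz.
#' @param stiffness torsional stiffness (N·m/rad); `NULL` auto-calibrates.
#' @param viscous viscous damping (N·m·s/rad); `NULL` sets it to contribute
#'   10% of the torque amplitude.
#' @param noise_sd_torque additive torque noise sd (N·m); `NULL` uses 1% of
#'   the torque amplitude.
#' @return a [torque_trace()] with `meta$frequency_hz = f`.
#' @export
synth_torque_trace <- function(patient, f, fs = 1000, duration = 25,
                               rom_deg = 40, move_hz = 1,
                               stiffness = NULL, viscous = NULL,
                               noise_sd_torque = NULL,
                               seed = patient$rng_seed) {
  stopifnot(inherits(patient, "virtual_patient"))
  theta_amp <- rom_deg * pi / 180
  omega <- 2 * pi * move_hz
  a_target <- pi / 2 * true_rigidity(patient, f)  # torque amplitude giving RoMaR = r(f)
  if (is.null(viscous)) viscous <- 0.1 * a_target / (theta_amp * omega)
  if (is.null(stiffness)) {
    s2 <- a_target^2 - (viscous * theta_amp * omega)^2
    stiffness <- sqrt(max(s2, 0)) / theta_amp
  }
  if (is.null(noise_sd_torque)) noise_sd_torque <- 0.01 * a_target
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  theta <- theta_amp * sin(omega * t)
  dtheta <- theta_amp * omega * cos(omega * t)
  noise <- if (noise_sd_torque > 0)
    with_seed(seed, stats::rnorm(length(t), 0, noise_sd_torque))
  else 0
  torque_trace(stiffness * theta + viscous * dtheta + noise, fs = fs,
               meta = list(frequency_hz = f, profile = patient$profile))
}

#' Simulate one current-vs-previous preference choice
#'
#' The patient prefers the current setting with probability
#' `Phi((v(current) - v(previous)) / (sqrt(2) * pref_noise))`, the probit
#' choice model applied to the latent value function.
#'
#' @inheritParams measure_romar
#' @param f_current,f_previous the two frequencies being compared (Hz).
#' @return a list with `a` (preferred frequency) and `b` (the other).
#' @export
choose_preference <- function(patient, f_current, f_previous,
                              seed = patient$rng_seed) {
  stopifnot(inherits(patient, "virtual_patient"))
  p_cur <- preference_probability(patient_value(patient, f_current),
                                  patient_value(patient, f_previous),
                                  sigma_noise = patient$value_fn$pref_noise)
  cur_wins <- with_seed(seed, stats::runif(1)) < p_cur
  if (cur_wins) list(a = f_current, b = f_previous)
  else list(a = f_previous, b = f_current)
}

#' Read / write a virtual patient as JSON
#'
#' @param patient a [virtual_patient()].
#' @param path file path.
#' @return [read_patient_json()] returns a `virtual_patient`.
#' @export
write_patient_json <- function(patient, path) {
  obj <- list(format_version = "1.0", profile = patient$profile,
              rigidity_curve = patient$rigidity_curve,
              noise_sd = patient$noise_sd, ceiling = patient$ceiling,
              value_fn = patient$value_fn, rng_seed = patient$rng_seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patient_json
#' @export
read_patient_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(o$format_version))
    validation_error("patient JSON lacks a format_version field")
  if (!identical(o$format_version, "1.0"))
    dbs_error("dbstune_unsupported_version",
              sprintf("unsupported patient format_version '%s'", o$format_version))
  args <- c(o$rigidity_curve,
            list(noise_sd = o$noise_sd, ceiling = o$ceiling),
            o$value_fn)
  do.call(virtual_patient,
          c(list(profile = o$profile, rng_seed = o$rng_seed), args))
}
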