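#' Expected improvement for rigidity minimization
#'
#' Utility of sampling each candidate frequency, defined as the expected
#' amount by which a new RoMaR measurement would improve on the incumbent
#' (the minimum observed value): with `I = incumbent - mu(x)` and
#' `Z = I / sigma(x)`,
#' `u(x) = I * Phi(Z) + sigma(x) * phi(Z)` where `sigma(x) > 0`, and
#' `u(x) = 0` where `sigma(x) = 0`.
#'
#' @param pred a [predictive_distribution()].
#' @param incumbent best (minimum) observed RoMaR so far.
#' @return numeric vector of utilities, one per grid point; non-negative.
#' @export
expected_improvement <- function(pred, incumbent) {
  stopifnot(inherits(pred, "predictive_distribution"))
  improve <- incumbent - pred$mu
  u <- numeric(length(pred$mu))
  pos <- pred$sigma > 0
  z <- improve[pos] / pred$sigma[pos]
  u[pos] <- improve[pos] * stats::pnorm(z) + pred$sigma[pos] * stats::dnorm(z)
  pmax(u, 0)
}

#' Select the next stimulation frequency to test
#'
#' Computes expected improvement over the candidate grid (restricted to the
#' tolerability ceiling) and proposes its argmax, ties broken toward the
#' lowest frequency. When the posterior standard deviation at the EI argmax
#' falls below `exploration_ratio * sqrt(noise_var)` the proposal is deemed
#' over-exploiting (it could not be distinguished from measurement noise)
#' and the maximum-posterior-variance grid point is selected instead for
#' that iteration.
#'
#' @param model a fitted [gp_model()].
#' @param grid candidate frequencies in Hz.
#' @param ceiling tolerability ceiling in Hz; grid points above it are
#'   infeasible.
#' @param exploration_ratio exploration/exploitation balance (default 0.5).
#' @return an object of class `acquisition_result`: list with `grid`,
#'   `utility`, `x_next`, `incumbent`, `overexploit_flag`.
#' @export
select_next_frequency <- function(model, grid, ceiling = Inf,
                                  exploration_ratio = 0.5) {
  stopifnot(inherits(model, "gp_model"))
  grid <- as.numeric(grid)
  feasible <- grid[grid <= ceiling]
  if (length(feasible) == 0L)
    no_feasible_frequency(sprintf("no candidate frequency at or below %g Hz", ceiling))
  feasible <- sort(feasible)
  pred <- gp_predict(model, feasible)
  incumbent <- if (nrow(model$data)) min(model$data$romar) else model$mean_const
  u <- expected_improvement(pred, incumbent)
  tol <- 1e-12 * max(1, max(u))
  idx <- which(u >= max(u) - tol)[1]          # feasible sorted: first = lowest Hz
  overexploit <- FALSE
  if (pred$sigma[idx] < exploration_ratio * sqrt(model$params$noise_var)) {
    overexploit <- TRUE
    stol <- 1e-12 * max(1, max(pred$sigma))
    idx <- which(pred$sigma >= max(pred$sigma) - stol)[1]
  }
  structure(list(grid = feasible, utility = u, x_next = feasible[idx],
                 incumbent = incumbent, overexploit_flag = overexploit),
            class = "acquisition_result")
}

#' Pseudorandom brute-force frequency schedule
#'
#' Orders the full stimulation-frequency grid pseudorandomly (seeded) and
#' adds one measurement at the participant's clinical frequency at the
#' beginning and at the end, as in the exhaustive first-visit protocol.
#'
#' @param fmin,fmax grid limits in Hz.
#' @param step grid step in Hz; must divide `fmax - fmin`.
#' @param clinical_freq the participant's clinical frequency in Hz, or
#'   `NULL` to omit the repeats.
#' @param seed integer seed for the pseudorandom order.
#' @return numeric vector of frequencies in test order (grid frequencies
#'   plus the two clinical repeats when requested).
#' @export
brute_force_schedule <- function(fmin = 10, fmax = 185, step = 5,
                                 clinical_freq = NULL, seed = 1) {
  if (fmin > fmax) invalid_parameter("`fmin` must not exceed `fmax`")
  if (step <= 0) invalid_parameter("`step` must be > 0")
  if (abs((fmax - fmin) / step - round((fmax - fmin) / step)) > 1e-9)
    invalid_parameter("`step` must divide fmax - fmin")
  grid <- seq(fmin, fmax, by = step)
  order <- with_seed(seed, sample(grid))
  c(clinical_freq, order, clinical_freq)
}

#' Session configuration for a BayesOpt programming visit
#'
#' Defaults follow the visit-2 protocol: four seed frequencies (30, 80, 90,
#' 140 Hz), eight algorithm-selected iterations on a 5 Hz grid from 10 to
#' 185 Hz, exploration ratio 0.5, preference querying on.
#'
#' @param seeds seed frequencies in Hz.
#' @param iterations number of BayesOpt iterations after seeding.
#' @param fmin,fmax,step candidate grid in Hz.
#' @param exploration_ratio see [select_next_frequency()].
#' @param restarts hyperparameter-fit restarts per refit.
#' @param rng_seed integer master seed for the session.
#' @param preference_enabled ask current-vs-previous preference after every
#'   measurement from the second onward.
#' @param ceiling initial tolerability ceiling in Hz.
#' @return an object of class `session_config`.
#' @export
session_config <- function(seeds = c(30, 80, 90, 140), iterations = 8,
                           fmin = 10, fmax = 185, step = 5,
                           exploration_ratio = 0.5, restarts = 8,
                           rng_seed = 1, preference_enabled = TRUE,
                           ceiling = Inf) {
  bad <- character()
  aligned <- function(f) abs((f - fmin) / step - round((f - fmin) / step)) < 1e-9
  if (!all(vapply(seeds, aligned, TRUE))) bad <- c(bad, "seeds")
  if (fmin > fmax) bad <- c(bad, "fmin", "fmax")
  if (iterations < 0) bad <- c(bad, "iterations")
  if (length(bad))
    validation_error(sprintf("invalid session config fields: %s",
                             paste(unique(bad), collapse = ", ")),
                     fields = unique(bad))
  structure(list(seeds = as.numeric(seeds), iterations = as.integer(iterations),
                 fmin = fmin, fmax = fmax, step = step,
                 exploration_ratio = exploration_ratio,
                 restarts = as.integer(restarts),
                 rng_seed = as.integer(rng_seed),
                 preference_enabled = isTRUE(preference_enabled),
                 ceiling = ceiling),
            class = "session_config")
}

#' Run one full BayesOpt programming session
#'
#' Executes the visit-2 protocol against a virtual patient: measure RoMaR at
#' each seed frequency, freeze the GP prior mean at the mean of the seed
#' values, then iterate refit-hyperparameters / predict /
#' [select_next_frequency()] / measure. After every measurement from the
#' second onward (seeds included) the patient is asked whether they prefer
#' the current or the previous setting. An intolerable response lowers the
#' tolerability ceiling: the offending frequency and everything above it are
#' removed from the candidate grid and the iteration re-selects, so a
#' completed session always has `length(seeds) + iterations` measurements.
#'
#' @param patient a [virtual_patient()].
#' @param config a [session_config()]; its `rng_seed` drives every source of
#'   randomness through named child streams, so identical inputs give
#'   bitwise-identical sessions.
#' @return an object of class `session_state`: list with `config`,
#'   `history` (an [observation_set()] with acquisition metadata columns),
#'   `preferences` (data.frame `step_index, frequency_a_hz, frequency_b_hz,
#'   winner`), `model` (final refitted [gp_model()]), `mean_const`,
#'   `ceiling` and `status`.
#' @export
run_session <- function(patient, config = session_config()) {
  stopifnot(inherits(patient, "virtual_patient"),
            inherits(config, "session_config"))
  seed <- config$rng_seed
  ceiling <- min(config$ceiling, config$fmax)
  history <- data.frame(frequency_hz = numeric(), romar = numeric(),
                        source = character(), order_index = integer(),
                        utility_argmax = numeric(),
                        overexploit_flag = logical(), ceiling = numeric())
  prefs <- empty_preferences()
  step_i <- 0L

  measure <- function(f) {
    measure_romar(patient, f, seed = child_seed(seed, paste0("measure/", step_i)))
  }
  ask_pref <- function(f_cur, f_prev) {
    choose_preference(patient, f_cur, f_prev,
                      seed = child_seed(seed, paste0("pref/", step_i)))
  }
  record <- function(f, y, src, util = NA_real_, flag = FALSE) {
    step_i <<- step_i + 1L
    history[nrow(history) + 1L, ] <<- list(f, y, src, step_i, util, flag, ceiling)
    if (config$preference_enabled && step_i > 1L) {
      prev <- history$frequency_hz[step_i - 1L]
      pair <- ask_pref(f, prev)
      prefs[nrow(prefs) + 1L, ] <<- list(step_i - 1L, f, prev,
                                         if (pair$a == f) "a" else "b")
    }
  }

  for (f in config$seeds) {
    if (f > ceiling) next  # seed above a known ceiling is skipped, not tested
    y <- tryCatch(measure(f), dbstune_intolerable = function(e) e)
    if (inherits(y, "dbstune_intolerable")) {
      ceiling <- f - config$step
      next
    }
    record(f, y, "seed")
  }
  if (nrow(history) == 0L)
    no_feasible_frequency("no seed frequency is below the tolerability ceiling")
  mean_const <- mean(history$romar)  # frozen after seeding

  for (it in seq_len(config$iterations)) {
    repeat {
      obs <- observation_set(history$frequency_hz, history$romar,
                             history$source, history$order_index)
      params <- fit_hyperparameters(obs, mean_const = mean_const,
                                    restarts = config$restarts,
                                    seed = child_seed(seed, paste0("fit/", it)))
      model <- gp_model(params, obs, mean_const = mean_const)
      grid <- seq(config$fmin, min(config$fmax, ceiling), by = config$step)
      acq <- select_next_frequency(model, grid, ceiling = ceiling,
                                   exploration_ratio = config$exploration_ratio)
      y <- tryCatch(measure(acq$x_next), dbstune_intolerable = function(e) e)
      if (inherits(y, "dbstune_intolerable")) {
        ceiling <- acq$x_next - config$step
        if (ceiling < config$fmin)
          no_feasible_frequency("every candidate frequency is intolerable")
        next
      }
      record(acq$x_next, y, "bayesopt", max(acq$utility), acq$overexploit_flag)
      break
    }
  }

  obs <- observation_set(history$frequency_hz, history$romar,
                         history$source, history$order_index)
  params <- fit_hyperparameters(obs, mean_const = mean_const,
                                restarts = config$restarts,
                                seed = child_seed(seed, "fit/final"))
  structure(list(config = config, history = history, preferences = prefs,
                 model = gp_model(params, obs, mean_const = mean_const),
                 mean_const = mean_const, ceiling = ceiling,
                 status = "completed"),
            class = "session_state")
}

#' @export
print.session_state <- function(x, ...) {
  cat(sprintf(
    "<session_state> %d measurements (%d seeds + %d BayesOpt), %d preference records, ceiling %g Hz\n",
    nrow(x$history), sum(x$history$source == "seed"),
    sum(x$history$source == "bayesopt"), nrow(x$preferences), x$ceiling))
  invisible(x)
}

empty_preferences <- function() {
  data.frame(step_index = integer(), frequency_a_hz = numeric(),
             frequency_b_hz = numeric(), winner = character())
}
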