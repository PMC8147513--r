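#' Optimal stimulation frequency from a fitted model
#'
#' The frequency at which the GP posterior mean of rigidity is lowest; ties
#' break toward the lowest frequency.
#'
#' @param pred a [predictive_distribution()].
#' @return frequency in Hz.
#' @export
optimal_frequency <- function(pred) {
  stopifnot(inherits(pred, "predictive_distribution"))
  ord <- order(pred$grid)
  g <- pred$grid[ord]; mu <- pred$mu[ord]
  tol <- 1e-12 * max(1, max(abs(mu)))
  g[which(mu <= min(mu) + tol)[1]]
}

#' Frequency range indistinguishable from the minimum
#'
#' The model's convergence/precision metric: all grid frequencies whose
#' predicted rigidity lies within one posterior standard deviation of the
#' predicted minimum (`mu(x) <= mu_min + sigma_min`, one-sided above the
#' minimum). Two summaries are derived: `width`, the span of the contiguous
#' run of such frequencies containing the optimum, and `lower_distance`,
#' the distance from the optimum down to the lowest frequency of that run.
#'
#' @param pred a [predictive_distribution()].
#' @return an object of class `frequency_range_result`: list with `x_opt`,
#'   `mu_min`, `sigma_min`, `range_set` (all qualifying frequencies),
#'   `interval` (`c(lo, hi)` of the contiguous run), `width`,
#'   `lower_distance`.
#' @export
frequency_range <- function(pred) {
  stopifnot(inherits(pred, "predictive_distribution"))
  ord <- order(pred$grid)
  g <- pred$grid[ord]; mu <- pred$mu[ord]; sg <- pred$sigma[ord]
  tol <- 1e-12 * max(1, max(abs(mu)))
  i_opt <- which(mu <= min(mu) + tol)[1]
  mu_min <- mu[i_opt]; sigma_min <- sg[i_opt]
  member <- mu <= mu_min + sigma_min + tol
  lo <- i_opt; hi <- i_opt
  while (lo > 1L && member[lo - 1L]) lo <- lo - 1L
  while (hi < length(g) && member[hi + 1L]) hi <- hi + 1L
  structure(list(x_opt = g[i_opt], mu_min = mu_min, sigma_min = sigma_min,
                 range_set = g[member], interval = c(g[lo], g[hi]),
                 width = g[hi] - g[lo], lower_distance = g[i_opt] - g[lo]),
            class = "frequency_range_result")
}

#' @export
print.frequency_range_result <- function(x, ...) {
  cat(sprintf(
    "x_opt = %g Hz; range [%g, %g] Hz (width %g Hz, lower distance %g Hz)\n",
    x$x_opt, x$interval[1], x$interval[2], x$width, x$lower_distance))
  invisible(x)
}

# Fit a GP to an observation subset with the standard hyperparameter policy
# and return its frequency_range on the evaluation grid.
fit_and_range <- function(obs, grid, seed, restarts = 8) {
  params <- fit_hyperparameters(obs, restarts = restarts, seed = seed)
  frequency_range(gp_predict(gp_model(params, obs), grid))
}

# Pick the brute-force observations at given frequencies; when a frequency
# was measured more than once the earliest measurement is used. Duplicate
# selections are kept (repeats allowed).
pick_obs <- function(bf, freqs) {
  rows <- vapply(freqs, function(f) which(bf$frequency_hz == f)[1], 0L)
  if (anyNA(rows))
    invalid_parameter("selected frequency not present in the brute-force data")
  observation_set(bf$frequency_hz[rows], bf$romar[rows],
                  bf$source[rows], seq_along(rows))
}

#' Equal-interval subsampling of brute-force data
#'
#' Selects `n` frequencies approximately evenly spaced between 10 Hz and the
#' maximum tolerated/tested frequency, each rounded to the nearest tested
#' setting (midpoints round up, so 3 points to a 155 Hz ceiling select
#' 10, 85 and 155 Hz), fits a GP to the corresponding
#' brute-force measurements, and returns its [frequency_range()].
#'
#' @param bf an [observation_set()] containing the brute-force visit.
#' @param n number of frequencies to select (`>= 2`).
#' @param fmin lower end of the selection span (default 10 Hz).
#' @param grid evaluation grid; defaults to the tested frequencies.
#' @param seed seed for the (deterministic-policy) GP refit.
#' @return a `frequency_range_result` with attribute `"selected"` holding
#'   the selected frequencies.
#' @export
simulate_equal_interval <- function(bf, n, fmin = 10, grid = NULL, seed = 1) {
  if (n < 2) invalid_parameter("`n` must be at least 2")
  tested <- sort(unique(bf$frequency_hz))
  fmax <- max(tested)
  targets <- seq(fmin, fmax, length.out = n)
  sel <- vapply(targets, function(tf) {
    d <- abs(tested - tf)
    cand <- which(d <= min(d) + 1e-9)
    tested[cand[length(cand)]]  # midpoint ties round up (e.g. 82.5 -> 85 Hz)
  }, 0)
  if (is.null(grid)) grid <- tested
  out <- fit_and_range(pick_obs(bf, sel), grid, seed)
  attr(out, "selected") <- sel
  out
}

#' Random subsampling of brute-force data
#'
#' Draws `n` frequencies uniformly with replacement from the tested grid,
#' fits a GP, and records the frequency-range width; repeated `reps` times
#' with seeded child streams.
#'
#' @inheritParams simulate_equal_interval
#' @param reps number of random repetitions (default 50).
#' @param seed master seed; each repetition uses a named child stream.
#' @return list with `mean_width`, `sd_width` (0 when `reps = 1`), and the
#'   per-repetition `widths`.
#' @export
simulate_random <- function(bf, n, reps = 50, grid = NULL, seed = 1) {
  if (n < 2) invalid_parameter("`n` must be at least 2")
  tested <- sort(unique(bf$frequency_hz))
  if (is.null(grid)) grid <- tested
  widths <- vapply(seq_len(reps), function(r) {
    sel <- with_seed(child_seed(seed, paste0("random/", n, "/", r)),
                     sample(tested, n, replace = TRUE))
    fit_and_range(pick_obs(bf, sel), grid,
                  seed = child_seed(seed, paste0("fit/", n, "/", r)))$width
  }, 0)
  list(mean_width = mean(widths),
       sd_width = if (reps > 1) stats::sd(widths) else 0,
       widths = widths)
}

#' Sampling-efficiency report
#'
#' Tabulates the frequency-range width (and lower distance / optimum) per
#' method and sample count, reproducing the efficiency comparison between
#' BayesOpt, equal-interval and random frequency selection. BayesOpt rows
#' are computed from the prefixes of a completed session's history (one row
#' per measurement; widths are `NA` until two distinct frequencies have
#' been measured). Equal-interval and random rows subsample the brute-force
#' data at each `n`.
#'
#' @param bf an [observation_set()] from the brute-force visit (`NULL` to
#'   skip the subsampling methods).
#' @param session a `session_state` from [run_session()] (`NULL` to skip
#'   the BayesOpt rows).
#' @param n_values sample counts for the subsampling methods.
#' @param reps random-selection repetitions per `n`.
#' @param grid evaluation grid; defaults to the brute-force tested
#'   frequencies (or the session grid).
#' @param seed master seed.
#' @return data.frame with columns
#'   `method, n, rep, width_hz, lower_distance_hz, x_opt_hz`.
#' @export
efficiency_report <- function(bf = NULL, session = NULL,
                              n_values = c(3, 6, 12, 24), reps = 50,
                              grid = NULL, seed = 1) {
  if (is.null(grid)) {
    grid <- if (!is.null(bf)) sort(unique(bf$frequency_hz))
    else seq(session$config$fmin, min(session$config$fmax, session$ceiling),
             by = session$config$step)
  }
  rows <- list()
  add <- function(method, n, rep, fr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, n = n, rep = rep,
      width_hz = if (is.null(fr)) NA_real_ else fr$width,
      lower_distance_hz = if (is.null(fr)) NA_real_ else fr$lower_distance,
      x_opt_hz = if (is.null(fr)) NA_real_ else fr$x_opt)
  }
  if (!is.null(session)) {
    h <- session$history
    for (n in seq_len(nrow(h))) {
      sub <- observation_set(h$frequency_hz[1:n], h$romar[1:n],
                             h$source[1:n], h$order_index[1:n])
      fr <- if (n >= 2 && length(unique(sub$frequency_hz)) >= 2)
        fit_and_range(sub, grid, seed = child_seed(seed, paste0("bo/", n)))
      else NULL
      add("bayesopt", n, 1L, fr)
    }
  }
  if (!is.null(bf)) {
    n_values <- pmin(n_values, length(unique(bf$frequency_hz)))
    for (n in unique(n_values)) {
      add("equal_interval", n, 1L,
          simulate_equal_interval(bf, n, grid = grid,
                                  seed = child_seed(seed, paste0("ei/", n))))
      for (r in seq_len(reps)) {
        sel <- with_seed(child_seed(seed, paste0("random/", n, "/", r)),
                         sample(sort(unique(bf$frequency_hz)), n, replace = TRUE))
        add("random", n, r,
            fit_and_range(pick_obs(bf, sel), grid,
                          seed = child_seed(seed, paste0("fit/", n, "/", r))))
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the brute-force visit against a virtual patient
#'
#' Executes [brute_force_schedule()] on a virtual patient: frequencies are
#' tested in the pseudorandom order; an intolerable response removes all
#' untested frequencies above the new ceiling from the remaining order.
#'
#' @param patient a [virtual_patient()].
#' @param fmin,fmax,step grid in Hz.
#' @param clinical_freq clinical frequency repeated at start and end
#'   (`NULL` to omit).
#' @param seed master seed (order and measurement noise).
#' @return an [observation_set()] with sources `brute_force` /
#'   `clinical_repeat`.
#' @export
run_brute_force <- function(patient, fmin = 10, fmax = 185, step = 5,
                            clinical_freq = NULL, seed = 1) {
  stopifnot(inherits(patient, "virtual_patient"))
  sched <- brute_force_schedule(fmin, fmax, step, clinical_freq,
                                seed = child_seed(seed, "order"))
  is_clin <- !is.null(clinical_freq) &
    seq_along(sched) %in% c(1L, length(sched)) &
    sched %in% clinical_freq
  ceiling_hz <- patient$ceiling
  out_f <- numeric(); out_y <- numeric(); out_src <- character()
  k <- 0L
  for (i in seq_along(sched)) {
    f <- sched[i]
    if (f > ceiling_hz) next  # dropped after an intolerable event
    k <- k + 1L
    y <- tryCatch(
      measure_romar(patient, f, seed = child_seed(seed, paste0("measure/", k))),
      dbstune_intolerable = function(e) e)
    if (inherits(y, "dbstune_intolerable")) {
      ceiling_hz <- f - step
      next
    }
    out_f <- c(out_f, f); out_y <- c(out_y, y)
    out_src <- c(out_src, if (is_clin[i]) "clinical_repeat" else "brute_force")
  }
  observation_set(out_f, out_y, out_src)
}

#' Write an efficiency report to CSV
#'
#' Column layout: `method,n,rep,width_hz,lower_distance_hz,x_opt_hz`.
#' @param report data.frame from [efficiency_report()].
#' @param path output path.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
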