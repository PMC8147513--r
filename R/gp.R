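#' Matérn kernel hyperparameters
#'
#' @param ell length-constant in Hz; controls how quickly correlation between
#'   rigidity at two stimulation frequencies decays with their separation.
#' @param signal_var kernel output variance (RoMaR squared).
#' @param noise_var observation noise variance (RoMaR squared).
#' @param nu Matérn smoothness order; 3/2 gives once-differentiable sample
#'   paths, coarse data but a smooth trend.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(ell = 20, signal_var = 1, noise_var = 0, nu = 1.5) {
  if (!is.numeric(ell) || ell <= 0) invalid_parameter("`ell` must be > 0")
  if (!is.numeric(signal_var) || signal_var <= 0)
    invalid_parameter("`signal_var` must be > 0")
  if (!is.numeric(noise_var) || noise_var < 0)
    invalid_parameter("`noise_var` must be >= 0")
  if (!is.numeric(nu) || nu <= 0) invalid_parameter("`nu` must be > 0")
  structure(list(nu = nu, ell = ell, signal_var = signal_var,
                 noise_var = noise_var), class = "kernel_params")
}

#' Matérn covariance between stimulation frequencies
#'
#' For `nu = 3/2` the closed form
#' `signal_var * (1 + sqrt(3) r / ell) * exp(-sqrt(3) r / ell)` is used; for
#' general `nu` the Gamma/Bessel form
#' `signal_var * 2^(1-nu)/Gamma(nu) * s^nu * K_nu(s)` with
#' `s = sqrt(2 nu) r / ell` (K_nu the modified Bessel function of the second
#' kind). The two agree at `nu = 3/2`.
#'
#' @param xi,xj frequencies in Hz (vectors are recycled elementwise).
#' @param params a [kernel_params()].
#' @return covariance value(s).
#' @export
matern_kernel <- function(xi, xj, params) {
  stopifnot(inherits(params, "kernel_params"))
  r <- abs(xi - xj)
  matern_of_r(r, params)
}

# Covariance as a function of distance; vectorized over r.
matern_of_r <- function(r, params) {
  ell <- params$ell; sv <- params$signal_var; nu <- params$nu
  if (isTRUE(all.equal(nu, 1.5))) {
    s <- sqrt(3) * r / ell
    return(sv * (1 + s) * exp(-s))
  }
  s <- sqrt(2 * nu) * r / ell
  out <- numeric(length(s))
  zero <- s == 0
  out[zero] <- sv
  sz <- s[!zero]
  out[!zero] <- sv * 2^(1 - nu) / gamma(nu) * sz^nu * besselK(sz, nu)
  out
}

# n x m cross-covariance matrix between frequency vectors.
matern_cov <- function(x1, x2, params) {
  r <- abs(outer(x1, x2, "-"))
  matrix(matern_of_r(r, params), nrow = length(x1))
}

#' Build an observation set of (frequency, RoMaR) pairs
#'
#' @param frequency_hz stimulation frequencies in Hz.
#' @param romar RoMaR values.
#' @param source provenance of each observation: one of `"seed"`,
#'   `"bayesopt"`, `"brute_force"`, `"clinical_repeat"`.
#' @param order_index acquisition order (defaults to row order).
#' @return a data.frame of class `observation_set`.
#' @export
observation_set <- function(frequency_hz, romar,
                            source = "brute_force",
                            order_index = seq_along(frequency_hz)) {
  ok <- c("seed", "bayesopt", "brute_force", "clinical_repeat")
  source <- rep_len(as.character(source), length(frequency_hz))
  if (!all(source %in% ok))
    invalid_parameter(sprintf("`source` must be one of %s",
                              paste(ok, collapse = ", ")))
  if (length(romar) != length(frequency_hz))
    invalid_parameter("`frequency_hz` and `romar` lengths differ")
  df <- data.frame(frequency_hz = as.numeric(frequency_hz),
                   romar = as.numeric(romar),
                   source = source,
                   order_index = as.integer(order_index))
  class(df) <- c("observation_set", "data.frame")
  df
}

#' Read / write observation CSV
#'
#' Column layout: `frequency_hz,romar,source,order_index`.
#' @param path CSV path.
#' @return [read_observations_csv()] returns an [observation_set()].
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frequency_hz", "romar")
  if (!all(need %in% names(df)))
    validation_error("observations CSV needs frequency_hz and romar columns",
                     fields = setdiff(need, names(df)))
  if (is.null(df$source)) df$source <- "brute_force"
  if (is.null(df$order_index)) df$order_index <- seq_len(nrow(df))
  observation_set(df$frequency_hz, df$romar, df$source, df$order_index)
}

#' @rdname read_observations_csv
#' @param obs an [observation_set()].
#' @export
write_observations_csv <- function(obs, path) {
  utils::write.csv(as.data.frame(obs)[, c("frequency_hz", "romar", "source",
                                          "order_index")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Cholesky of K with escalating diagonal jitter (1e-10 .. 1e-4 of signal_var).
chol_jitter <- function(K, signal_var) {
  for (j in c(0, 10^seq(-10, -4))) {
    U <- tryCatch(chol(K + diag(j * signal_var, nrow(K))), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = j * signal_var))
  }
  numerical_failure("covariance matrix not positive definite after jitter escalation")
}

# Negative log marginal likelihood of the centered targets y0 under the
# Matérn GP with parameters `p` (list with ell, signal_var, noise_var).
gp_nll <- function(y0, x, p) {
  n <- length(y0)
  K <- matern_cov(x, x, p) + diag(p$noise_var, n)
  cj <- tryCatch(chol_jitter(K, p$signal_var), error = function(e) NULL)
  if (is.null(cj)) return(1e10)
  U <- cj$U
  alpha <- backsolve(U, forwardsolve(t(U), y0))
  as.numeric(0.5 * sum(y0 * alpha) + sum(log(diag(U))) + n / 2 * log(2 * pi))
}

#' Fit GP hyperparameters by maximum marginal likelihood
#'
#' Maximizes the log marginal likelihood of the (mean-centered) RoMaR values
#' over the non-fixed hyperparameters, using multi-start bounded
#' quasi-Newton (`L-BFGS-B`) on log-parameters. Deterministic given `data`
#' and `seed`.
#'
#' @param data an [observation_set()] with at least two distinct frequencies.
#' @param fixed named list pinning any of `ell`, `signal_var`, `noise_var`.
#' @param bounds named list of `c(lower, upper)` intervals overriding the
#'   defaults: `ell` in `[2.5, 350]` Hz, `signal_var` in
#'   `[1e-4, 100] * var(y)`, `noise_var` in `[1e-6, 10] * var(y)`.
#' @param mean_const constant prior mean subtracted before fitting; defaults
#'   to `mean(data$romar)`.
#' @param restarts number of random multi-start initializations.
#' @param seed integer seed controlling the restarts.
#' @return a [kernel_params()] (with `nu = 3/2`).
#' @export
fit_hyperparameters <- function(data, fixed = list(), bounds = list(),
                                mean_const = NULL, restarts = 8, seed = 1) {
  stopifnot(inherits(data, "observation_set") || is.data.frame(data))
  x <- data$frequency_hz
  y <- data$romar
  if (length(x) < 2L)
    insufficient_data("need at least 2 observations to fit hyperparameters")
  if (length(unique(x)) < 2L)
    degenerate_design("all observations share one frequency; cannot identify a length-constant")
  if (is.null(mean_const)) mean_const <- mean(y)
  y0 <- y - mean_const

  free <- setdiff(c("ell", "signal_var", "noise_var"), names(fixed))
  if (length(free) == 0L) {
    return(kernel_params(ell = fixed$ell, signal_var = fixed$signal_var,
                         noise_var = fixed$noise_var))
  }
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- max(mean(y^2), 1)
  def_bounds <- list(ell = c(2.5, 350),
                     signal_var = c(1e-4 * vy, 100 * vy),
                     noise_var = c(1e-6 * vy, 10 * vy))
  for (nm in names(bounds)) def_bounds[[nm]] <- bounds[[nm]]
  lb <- log(vapply(free, function(nm) def_bounds[[nm]][1], 0))
  ub <- log(vapply(free, function(nm) def_bounds[[nm]][2], 0))

  make_params <- function(theta) {
    p <- list(ell = fixed$ell, signal_var = fixed$signal_var,
              noise_var = fixed$noise_var, nu = 1.5)
    p[free] <- as.list(exp(theta))
    p
  }
  obj <- function(theta) gp_nll(y0, x, make_params(theta))

  starts <- with_seed(seed, {
    s0 <- (lb + ub) / 2
    more <- if (restarts > 1)
      t(replicate(restarts - 1, stats::runif(length(free), lb, ub)))
    else NULL
    rbind(s0, more)
  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    numerical_failure("hyperparameter optimization failed from every start")
  p <- make_params(best$par)
  kernel_params(ell = p$ell, signal_var = p$signal_var,
                noise_var = p$noise_var, nu = 1.5)
}

#' Construct a fitted Gaussian-process model over stimulation frequency
#'
#' Binds kernel hyperparameters, a constant prior mean and the observations,
#' caching the Cholesky factorization of `K + noise_var * I` for prediction.
#'
#' @param params a [kernel_params()].
#' @param data an [observation_set()] (may be empty for the prior).
#' @param mean_const constant prior mean in RoMaR units; in the session
#'   protocol this is the mean of the four seed measurements.
#' @return an object of class `gp_model`.
#' @export
gp_model <- function(params, data = observation_set(numeric(), numeric()),
                     mean_const = if (nrow(data)) mean(data$romar) else 0) {
  stopifnot(inherits(params, "kernel_params"))
  x <- data$frequency_hz
  n <- length(x)
  cache <- NULL
  if (n > 0) {
    K <- matern_cov(x, x, params) + diag(params$noise_var, n)
    cj <- chol_jitter(K, params$signal_var)
    y0 <- data$romar - mean_const
    alpha <- backsolve(cj$U, forwardsolve(t(cj$U), y0))
    cache <- list(U = cj$U, alpha = alpha, jitter = cj$jitter)
  }
  structure(list(params = params, mean_const = mean_const, data = data,
                 chol = cache), class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf(
    "<gp_model> Matern nu=%g, ell=%.3g Hz, signal_var=%.3g, noise_var=%.3g; n=%d, mean=%.3g\n",
    x$params$nu, x$params$ell, x$params$signal_var, x$params$noise_var,
    nrow(x$data), x$mean_const))
  invisible(x)
}

#' GP predictive distribution on a frequency grid
#'
#' Posterior mean and standard deviation of RoMaR at each candidate
#' frequency: `mu(x) = mean_const + k' (K + noise_var I)^-1 (y - mean_const)`
#' and `sigma^2(x) = k(x,x) - k' (K + noise_var I)^-1 k`, floored at zero.
#' With no observations the prior (`mean_const`, `sqrt(signal_var)`) is
#' returned.
#'
#' @param model a [gp_model()].
#' @param grid candidate frequencies in Hz.
#' @return an object of class `predictive_distribution`: list with `grid`,
#'   `mu` and `sigma`.
#' @export
gp_predict <- function(model, grid) {
  stopifnot(inherits(model, "gp_model"))
  grid <- as.numeric(grid)
  p <- model$params
  if (is.null(model$chol)) {
    return(predictive_distribution(grid,
                                   rep(model$mean_const, length(grid)),
                                   rep(sqrt(p$signal_var), length(grid))))
  }
  kg <- matern_cov(model$data$frequency_hz, grid, p)  # n x m
  mu <- model$mean_const + drop(crossprod(kg, model$chol$alpha))
  w <- forwardsolve(t(model$chol$U), kg)
  s2 <- pmax(p$signal_var - colSums(w^2), 0)
  predictive_distribution(grid, mu, sqrt(s2))
}

#' Bundle a predictive distribution
#'
#' @param grid candidate frequencies in Hz.
#' @param mu posterior mean per grid point.
#' @param sigma posterior standard deviation per grid point (must be >= 0).
#' @return an object of class `predictive_distribution`.
#' @export
predictive_distribution <- function(grid, mu, sigma) {
  if (length(mu) != length(grid) || length(sigma) != length(grid))
    invalid_parameter("`grid`, `mu`, `sigma` must have equal length")
  if (any(sigma < 0)) invalid_parameter("`sigma` must be non-negative")
  structure(list(grid = as.numeric(grid), mu = as.numeric(mu),
                 sigma = as.numeric(sigma)),
            class = "predictive_distribution")
}

#' Serialize / deserialize a GP model to JSON
#'
#' @param model a [gp_model()].
#' @param path file path.
#' @return [read_gp_json()] returns a `gp_model`.
#' @export
write_gp_json <- function(model, path) {
  obj <- list(format_version = "1.0",
              params = unclass(model$params),
              mean_const = model$mean_const,
              data = as.data.frame(model$data))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gp_json
#' @export
read_gp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$params
  data <- if (length(obj$data))
    observation_set(obj$data$frequency_hz, obj$data$romar,
                    obj$data$source, obj$data$order_index)
  else observation_set(numeric(), numeric())
  gp_model(kernel_params(ell = p$ell, signal_var = p$signal_var,
                         noise_var = p$noise_var, nu = p$nu),
           data, mean_const = obj$mean_const)
}
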