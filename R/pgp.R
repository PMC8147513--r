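#' Probit probability that one setting is preferred over another
#'
#' Under the latent value model `v(x) = f(x) + eps`,
#' `eps ~ N(0, sigma_noise^2)`, the probability that setting `a` is
#' preferred to setting `b` is
#' `Phi((f(a) - f(b)) / (sqrt(2) * sigma_noise))`.
#'
#' @param fa,fb latent values of the two settings.
#' @param sigma_noise preference noise scale (fixed at 1 when fitting).
#' @return probability in `[0, 1]`.
#' @export
preference_probability <- function(fa, fb, sigma_noise = 1) {
  stats::pnorm((fa - fb) / (sqrt(2) * sigma_noise))
}

#' Build a preference dataset of ranked pairs
#'
#' @param a frequencies (Hz) of the preferred setting in each comparison.
#' @param b frequencies (Hz) of the non-preferred setting.
#' @param step_index when in the session each comparison was asked.
#' @return a data.frame of class `preference_dataset` with columns `a`,
#'   `b`, `step_index`; `a` is always the winner.
#' @export
preference_dataset <- function(a, b, step_index = seq_along(a)) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    invalid_parameter("`a` and `b` must have the same length")
  if (any(a == b))
    invalid_parameter("a comparison must involve two distinct frequencies")
  df <- data.frame(a = a, b = b, step_index = as.integer(step_index))
  class(df) <- c("preference_dataset", "data.frame")
  df
}

#' Extract ranked pairs from a session's preference records
#'
#' @param state a `session_state` from [run_session()], or its
#'   `preferences` data.frame (`frequency_a_hz`, `frequency_b_hz`,
#'   `winner`).
#' When the algorithm re-tests the frequency it just measured, the
#' current-vs-previous question compares a setting to itself; such records
#' are kept in the session log (the question was asked) but dropped here,
#' since a self-comparison carries no information about the value function.
#'
#' @return a [preference_dataset()] with the winner first in each pair.
#' @export
session_preferences <- function(state) {
  df <- if (inherits(state, "session_state")) state$preferences else state
  df <- df[df$frequency_a_hz != df$frequency_b_hz, , drop = FALSE]
  if (nrow(df) == 0L) return(preference_dataset(numeric(), numeric()))
  win <- ifelse(df$winner == "a", df$frequency_a_hz, df$frequency_b_hz)
  lose <- ifelse(df$winner == "a", df$frequency_b_hz, df$frequency_a_hz)
  preference_dataset(win, lose, df$step_index)
}

# log Phi, its first derivative ratio h = phi/Phi, evaluated stably.
log_phi_ratio <- function(z) {
  exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
}

# Log posterior (up to a constant), gradient, and the likelihood-curvature
# matrix C for latent values f at the m distinct compared frequencies.
# ia/ib index the winner/loser of each pair into f; Kinv is the precision of
# the GP prior over those frequencies.
pgp_objective <- function(f, ia, ib, Kinv, sigma_noise = 1) {
  s <- 1 / (sqrt(2) * sigma_noise)
  z <- s * (f[ia] - f[ib])
  loglik <- sum(stats::pnorm(z, log.p = TRUE))
  as.numeric(-0.5 * crossprod(f, Kinv %*% f) + loglik)
}

pgp_grad_C <- function(f, ia, ib, Kinv, sigma_noise = 1) {
  m <- length(f)
  s <- 1 / (sqrt(2) * sigma_noise)
  z <- s * (f[ia] - f[ib])
  h <- log_phi_ratio(z)
  g_lik <- numeric(m)
  w <- s * h
  for (i in seq_along(ia)) {
    g_lik[ia[i]] <- g_lik[ia[i]] + w[i]
    g_lik[ib[i]] <- g_lik[ib[i]] - w[i]
  }
  # curvature of -loglik: per pair s^2 * h(z) * (z + h(z)) on the 2x2 block
  cw <- s^2 * h * (z + h)
  C <- matrix(0, m, m)
  for (i in seq_along(ia)) {
    C[ia[i], ia[i]] <- C[ia[i], ia[i]] + cw[i]
    C[ib[i], ib[i]] <- C[ib[i], ib[i]] + cw[i]
    C[ia[i], ib[i]] <- C[ia[i], ib[i]] - cw[i]
    C[ib[i], ia[i]] <- C[ib[i], ia[i]] - cw[i]
  }
  list(grad = as.numeric(-Kinv %*% f + g_lik), C = C)
}

#' Fit the probit-GP latent value function by MAP
#'
#' Maximizes the log posterior `log P(f) + sum_i log Phi(Z_i)`, with
#' `Z_i = (f(a_i) - f(b_i)) / (sqrt(2) sigma_noise)` and a Matérn GP prior
#' over the distinct compared frequencies, by damped Newton–Raphson
#' (step-halving line search) until the gradient norm drops below `tol` or
#' `max_iter` iterations. The recursion can stall in poor basins from bad
#' starts, so `restarts` seeded random initializations (uniform on
#' `[-1, 1]` per coordinate) are run and the best objective wins, ties going
#' to the lowest restart index.
#'
#' @param pairs a [preference_dataset()] (winner in column `a`).
#' @param kernel a [kernel_params()] for the GP prior; by convention the
#'   length-constant is carried over from the same session's rigidity GP,
#'   with `signal_var = 1` (the latent scale is set by `sigma_noise`, not
#'   learned).
#' @param sigma_noise preference noise scale; fixed at 1, not learned.
#' @param restarts number of random initializations (default 25).
#' @param seed integer seed for the restarts.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter Newton iteration cap per restart.
#' @return an object of class `pgp_model`: `x_train` (distinct compared
#'   frequencies, sorted), `f_map` (latent values, centered to mean zero),
#'   `sigma_noise`, `kernel`, `C` (curvature of the negative log-likelihood
#'   at the MAP), `map_log_posterior`.
#' @export
fit_pgp_map <- function(pairs, kernel = kernel_params(signal_var = 1),
                        sigma_noise = 1, restarts = 25, seed = 1,
                        tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(pairs, "preference_dataset") || is.data.frame(pairs))
  if (nrow(pairs) < 1L)
    insufficient_data("need at least one preference pair")
  x_train <- sort(unique(c(pairs$a, pairs$b)))
  m <- length(x_train)
  ia <- match(pairs$a, x_train)
  ib <- match(pairs$b, x_train)
  K <- matern_cov(x_train, x_train, kernel)
  cj <- chol_jitter(K, kernel$signal_var)
  Kinv <- chol2inv(cj$U)

  newton <- function(f0) {
    f <- f0
    obj <- pgp_objective(f, ia, ib, Kinv, sigma_noise)
    for (iter in seq_len(max_iter)) {
      gc_ <- pgp_grad_C(f, ia, ib, Kinv, sigma_noise)
      if (sqrt(sum(gc_$grad^2)) < tol)
        return(list(f = f, obj = obj, converged = TRUE, C = gc_$C))
      H <- Kinv + gc_$C  # negative Hessian of the log posterior
      delta <- tryCatch(solve(H, gc_$grad), error = function(e) NULL)
      if (is.null(delta)) delta <- gc_$grad  # fall back to gradient ascent
      step <- 1
      repeat {
        f_new <- f + step * delta
        obj_new <- pgp_objective(f_new, ia, ib, Kinv, sigma_noise)
        if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
        step <- step / 2
        if (step < 1e-12) { f_new <- f; obj_new <- obj; break }
      }
      if (identical(f_new, f))
        return(list(f = f, obj = obj, converged = FALSE, C = gc_$C))
      f <- f_new; obj <- obj_new
    }
    gc_ <- pgp_grad_C(f, ia, ib, Kinv, sigma_noise)
    list(f = f, obj = obj, converged = sqrt(sum(gc_$grad^2)) < tol, C = gc_$C)
  }

  starts <- with_seed(seed,
    lapply(seq_len(restarts), function(i) stats::runif(m, -1, 1)))
  best <- NULL
  for (i in seq_len(restarts)) {
    res <- newton(starts[[i]])
    if (res$converged && (is.null(best) || res$obj > best$obj)) best <- res
  }
  if (is.null(best)) {
    objs <- vapply(starts, function(s) newton(s)$obj, 0)
    convergence_failure(sprintf(
      "Newton-Raphson failed to converge from all %d restarts (best objective %.6g)",
      restarts, max(objs)))
  }
  f_centered <- best$f - mean(best$f)
  structure(list(x_train = x_train, f_map = f_centered,
                 sigma_noise = sigma_noise, kernel = kernel,
                 C = best$C, map_log_posterior = best$obj),
            class = "pgp_model")
}

#' @export
print.pgp_model <- function(x, ...) {
  cat(sprintf("<pgp_model> %d compared frequencies, log posterior %.4g\n",
              length(x$x_train), x$map_log_posterior))
  invisible(x)
}

#' Predictive distribution of the latent preference value
#'
#' Posterior over the value function at new frequencies:
#' `mu(x) = k' K^-1 f_map` and
#' `sigma^2(x) = k(x,x) - k' (K + C^-1)^-1 k`, floored at zero. `C` is the
#' curvature of the negative log-likelihood at the MAP; when it is singular
#' (as it always is, the likelihood being translation invariant) a small
#' diagonal jitter is added before inversion, escalating as in the rigidity
#' GP.
#'
#' @param model a `pgp_model` from [fit_pgp_map()].
#' @param grid frequencies in Hz.
#' @return a [predictive_distribution()].
#' @export
pgp_predict <- function(model, grid) {
  stopifnot(inherits(model, "pgp_model"))
  grid <- as.numeric(grid)
  K <- matern_cov(model$x_train, model$x_train, model$kernel)
  cjK <- chol_jitter(K, model$kernel$signal_var)
  kg <- matern_cov(model$x_train, grid, model$kernel)
  mu <- drop(crossprod(kg, backsolve(cjK$U, forwardsolve(t(cjK$U), model$f_map))))

  Cinv <- inv_jitter(model$C)
  A <- K + Cinv
  cjA <- chol_jitter(A, model$kernel$signal_var)
  w <- forwardsolve(t(cjA$U), kg)
  s2 <- pmax(model$kernel$signal_var - colSums(w^2), 0)
  predictive_distribution(grid, mu, sqrt(s2))
}

# Inverse with escalating diagonal jitter (starting at 1e-8), for matrices
# that are PSD but may be singular.
inv_jitter <- function(M) {
  for (j in 10^seq(-8, -4)) {
    out <- tryCatch(chol2inv(chol(M + diag(j, nrow(M)))),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  numerical_failure("matrix inversion failed after jitter escalation")
}

#' Peak of the preference model
#'
#' The frequency at which the posterior mean of the latent value function is
#' largest; ties break toward the lowest frequency.
#'
#' @param pred a [predictive_distribution()] from [pgp_predict()].
#' @return frequency in Hz.
#' @export
preferred_frequency <- function(pred) {
  stopifnot(inherits(pred, "predictive_distribution"))
  ord <- order(pred$grid)
  g <- pred$grid[ord]; mu <- pred$mu[ord]
  tol <- 1e-12 * max(1, max(abs(mu)))
  g[which(mu >= max(mu) - tol)[1]]
}

#' Read / write preference CSV
#'
#' Column layout: `step_index,frequency_a_hz,frequency_b_hz,winner` with
#' `winner` in `{a, b}`.
#' @param path CSV path.
#' @return [read_preferences_csv()] returns a [preference_dataset()] with
#'   the winner first.
#' @export
read_preferences_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("step_index", "frequency_a_hz", "frequency_b_hz", "winner")
  if (!all(need %in% names(df)))
    validation_error("preference CSV needs step_index, frequency_a_hz, frequency_b_hz, winner",
                     fields = setdiff(need, names(df)))
  if (!all(df$winner %in% c("a", "b")))
    validation_error("`winner` must be 'a' or 'b'", fields = "winner")
  session_preferences(df)
}

#' @rdname read_preferences_csv
#' @param prefs a data.frame with the raw columns (e.g. a session's
#'   `preferences` element).
#' @export
write_preferences_csv <- function(prefs, path) {
  need <- c("step_index", "frequency_a_hz", "frequency_b_hz", "winner")
  utils::write.csv(prefs[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted pGP model to JSON
#'
#' @param model a `pgp_model` from [fit_pgp_map()].
#' @param path file path.
#' @return [read_pgp_json()] returns a `pgp_model`.
#' @export
write_pgp_json <- function(model, path) {
  obj <- list(format_version = "1.0",
              x_train = model$x_train, f_map = model$f_map,
              sigma_noise = model$sigma_noise,
              kernel = unclass(model$kernel),
              C = model$C, map_log_posterior = model$map_log_posterior)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pgp_json
#' @export
read_pgp_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(x_train = o$x_train, f_map = o$f_map,
                 sigma_noise = o$sigma_noise,
                 kernel = kernel_params(ell = o$kernel$ell,
                                        signal_var = o$kernel$signal_var,
                                        noise_var = o$kernel$noise_var,
                                        nu = o$kernel$nu),
                 C = matrix(unlist(o$C), nrow = length(o$x_train)),
                 map_log_posterior = o$map_log_posterior),
            class = "pgp_model")
}
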