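# Independent oracles used across test files. These deliberately avoid the
# package's own linear-algebra paths: covariances are assembled with outer()
# and conditioned with solve() on the explicit joint matrix.

# General-nu Matern via the Gamma/Bessel form (oracle for the nu=3/2 closed
# form used by the package).
matern_bessel_oracle <- function(r, ell, signal_var, nu) {
  ifelse(r == 0, signal_var, {
    s <- sqrt(2 * nu) * r / ell
    signal_var * 2^(1 - nu) / gamma(nu) * s^nu * besselK(s, nu)
  })
}

# Brute-force Gaussian conditioning: assemble the (n+m) joint covariance and
# condition the grid block on the (noisy) observation block.
gp_conditioning_oracle <- function(x, y, grid, params, mean_const) {
  kfun <- function(a, b) matern_kernel(a, b, params)
  K11 <- outer(x, x, kfun) + diag(params$noise_var, length(x))
  K12 <- outer(x, grid, kfun)
  K22 <- outer(grid, grid, kfun)
  mu <- mean_const + drop(t(K12) %*% solve(K11, y - mean_const))
  S <- K22 - t(K12) %*% solve(K11, K12)
  list(mu = mu, sigma = sqrt(pmax(diag(S), 0)))
}

# Exhaustive coarse-to-fine grid search of the pGP log posterior on a tiny
# instance. Valid refinement: the probit log posterior is strictly concave
# (Gaussian prior + log-concave likelihood), so the coarse optimum lies in
# the basin of the global one.
pgp_grid_oracle <- function(pairs, kernel, lim = 3, coarse = 0.1, fine = 0.005) {
  x_train <- sort(unique(c(pairs$a, pairs$b)))
  m <- length(x_train)
  stopifnot(m <= 3L)
  ia <- match(pairs$a, x_train); ib <- match(pairs$b, x_train)
  K <- outer(x_train, x_train, function(a, b) matern_kernel(a, b, kernel))
  Kinv <- solve(K + diag(1e-10, m))
  logpost <- function(X) {
    lp <- -0.5 * rowSums((X %*% Kinv) * X)
    for (i in seq_along(ia))
      lp <- lp + pnorm((X[, ia[i]] - X[, ib[i]]) / sqrt(2), log.p = TRUE)
    lp
  }
  X <- as.matrix(expand.grid(rep(list(seq(-lim, lim, coarse)), m)))
  b <- X[which.max(logpost(X)), ]
  X2 <- as.matrix(expand.grid(lapply(b, function(bi) bi + seq(-coarse, coarse, fine))))
  f <- X2[which.max(logpost(X2)), ]
  list(x_train = x_train, f_centered = unname(f - mean(f)))
}

# Simulate every pairwise comparison among `grid` once with the patient's
# probit choice model and fit a pGP to the outcomes.
exhaustive_preference_fit <- function(patient, grid, seed,
                                      kernel = kernel_params(ell = 20, signal_var = 1),
                                      restarts = 25) {
  prs <- t(utils::combn(grid, 2))
  a <- numeric(nrow(prs)); b <- numeric(nrow(prs))
  for (i in seq_len(nrow(prs))) {
    ch <- choose_preference(patient, prs[i, 1], prs[i, 2],
                            seed = child_seed(seed, paste0("pair/", i)))
    a[i] <- ch$a; b[i] <- ch$b
  }
  fit_pgp_map(preference_dataset(a, b), kernel, restarts = restarts, seed = seed)
}

# One observation per tested frequency (earliest measurement), sorted: the
# selection simulate_equal_interval converges to at n = number of settings.
pick_obs_for_test <- function(bf) {
  tested <- sort(unique(bf$frequency_hz))
  rows <- vapply(tested, function(f) which(bf$frequency_hz == f)[1], 0L)
  observation_set(bf$frequency_hz[rows], bf$romar[rows], bf$source[rows])
}

# Steady-state amplitude of a sinusoidal component in a filtered signal,
# estimated by least squares on the trailing portion of the trace.
fitted_amplitude <- function(trace, f, settle = 2) {
  keep <- trace$t >= settle
  X <- cbind(sin(2 * pi * f * trace$t[keep]), cos(2 * pi * f * trace$t[keep]))
  cf <- stats::lm.fit(X, trace$torque[keep])$coefficients
  sqrt(sum(cf^2))
}
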