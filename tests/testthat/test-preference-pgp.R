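test_that("probit preference probability follows the standard normal CDF", {
  expect_equal(preference_probability(1.3, 1.3), 0.5)
  expect_equal(preference_probability(sqrt(2), 0), pnorm(1), tolerance = 1e-9)
  expect_equal(preference_probability(sqrt(2), 0), 0.841345, tolerance = 1e-6)
  expect_equal(preference_probability(1e6, 0), 1)
  expect_equal(preference_probability(0, 1e6), 0)
  # translation invariance of the choice model
  expect_equal(preference_probability(2.4 + 7, 1.1 + 7),
               preference_probability(2.4, 1.1))
})

test_that("MAP fit orders latent values consistently with the choices", {
  kp <- kernel_params(ell = 20, signal_var = 1)
  one <- fit_pgp_map(preference_dataset(a = 90, b = 140), kp, seed = 1)
  expect_gt(one$f_map[one$x_train == 90], one$f_map[one$x_train == 140])
  # chain of four consistent comparisons over five inputs: the latent
  # ordering reproduces the expressed total order exactly
  freqs <- c(60, 80, 100, 120, 140)
  chain <- preference_dataset(a = freqs[1:4], b = freqs[2:5])  # 60>80>100>120>140
  m <- fit_pgp_map(chain, kp, seed = 2)
  expect_identical(order(m$f_map, decreasing = TRUE), seq_along(freqs))
  expect_equal(mean(m$f_map), 0, tolerance = 1e-12)
})

test_that("MAP solution matches the exhaustive grid-search oracle", {
  kp <- kernel_params(ell = 20, signal_var = 1)
  set.seed(77)
  for (case in 1:3) {
    x <- sort(sample(seq(10, 185, 5), 3))
    npairs <- sample(2:4, 1)
    idx <- replicate(npairs, sample(3, 2))
    pairs <- preference_dataset(a = x[idx[1, ]], b = x[idx[2, ]])
    fit <- fit_pgp_map(pairs, kp, seed = case)
    oracle <- pgp_grid_oracle(pairs, kp)
    expect_equal(fit$f_map, oracle$f_centered, tolerance = 0.05)
  }
})

test_that("the MAP objective dominates the zero vector and flips with the data", {
  kp <- kernel_params(ell = 25, signal_var = 1)
  set.seed(31)
  for (case in 1:5) {
    x <- sort(sample(seq(10, 185, 5), 4))
    a <- sample(x, 6, replace = TRUE)
    b <- vapply(a, function(ai) sample(setdiff(x, ai), 1), 0)
    pairs <- preference_dataset(a, b)
    fit <- fit_pgp_map(pairs, kp, seed = case, restarts = 10)
    # log posterior at the MAP beats the zero vector (the prior mode)
    x_train <- fit$x_train
    K <- outer(x_train, x_train, function(u, v) matern_kernel(u, v, kp))
    Kinv <- solve(K + diag(1e-10, length(x_train)))
    lp <- function(f) {
      -0.5 * drop(f %*% Kinv %*% f) +
        sum(pnorm((f[match(pairs$a, x_train)] - f[match(pairs$b, x_train)]) / sqrt(2),
                  log.p = TRUE))
    }
    expect_gte(fit$map_log_posterior, lp(numeric(length(x_train))))
    # reversing every pair negates the centered MAP
    flipped <- fit_pgp_map(preference_dataset(b, a), kp, seed = case, restarts = 10)
    expect_equal(flipped$f_map, -fit$f_map, tolerance = 1e-6)
  }
})

test_that("consistent exhaustive comparisons recover a random total order", {
  # frequencies well separated relative to the length-constant, so the
  # smoothness prior cannot override a consistent total order
  kp <- kernel_params(ell = 10, signal_var = 1)
  set.seed(8)
  for (case in 1:5) {
    x <- sort(sample(seq(10, 185, 25), 5))
    truth <- sample(x)  # best to worst
    rk <- function(f) match(f, truth)
    cmb <- t(combn(x, 2))
    a <- ifelse(rk(cmb[, 1]) < rk(cmb[, 2]), cmb[, 1], cmb[, 2])
    b <- ifelse(rk(cmb[, 1]) < rk(cmb[, 2]), cmb[, 2], cmb[, 1])
    m <- fit_pgp_map(preference_dataset(a, b), kp, seed = case, restarts = 10)
    expect_identical(m$x_train[order(m$f_map, decreasing = TRUE)], truth)
  }
})

test_that("pGP predictive distribution matches direct matrix assembly", {
  kp <- kernel_params(ell = 20, signal_var = 1)
  pairs <- preference_dataset(a = c(100, 120), b = c(80, 100))
  m <- fit_pgp_map(pairs, kp, seed = 4)
  grid <- c(70, 85, 100, 130, 160)
  pred <- pgp_predict(m, grid)
  # oracle: same printed formulas, assembled densely with solve()
  K <- outer(m$x_train, m$x_train, function(u, v) matern_kernel(u, v, kp))
  kg <- outer(m$x_train, grid, function(u, v) matern_kernel(u, v, kp))
  mu_o <- drop(t(kg) %*% solve(K + diag(1e-10, 3), m$f_map))
  Cinv <- solve(m$C + diag(1e-8, 3))
  s2_o <- pmax(1 - diag(t(kg) %*% solve(K + Cinv, kg)), 0)
  expect_equal(pred$mu, mu_o, tolerance = 1e-8)
  expect_equal(pred$sigma, sqrt(s2_o), tolerance = 1e-8)
  # information reduces variance below the prior at a compared frequency
  expect_lt(pred$sigma[grid == 100], 1)
})

test_that("without likelihood information the predictive variance is the prior", {
  kp <- kernel_params(ell = 20, signal_var = 1)
  m <- fit_pgp_map(preference_dataset(100, 80), kp, seed = 1)
  m$C <- matrix(0, 2, 2)     # C -> 0: C^-1 diverges, no information retained
  m$f_map <- c(0, 0)
  pred <- pgp_predict(m, c(80, 100, 140))
  expect_equal(pred$sigma, rep(1, 3), tolerance = 1e-3)
})

test_that("preferred_frequency takes the argmax with low tie-break", {
  expect_equal(preferred_frequency(
    predictive_distribution(c(70, 90, 110), c(0.1, 0.9, 0.3), rep(0.1, 3))), 90)
  expect_equal(preferred_frequency(
    predictive_distribution(c(70, 90, 110), rep(0.5, 3), rep(0.1, 3))), 70)
})

test_that("self-comparisons are logged but excluded from the fitting dataset", {
  prefs <- data.frame(step_index = 1:3,
                      frequency_a_hz = c(80, 100, 100),
                      frequency_b_hz = c(60, 100, 120),
                      winner = c("a", "a", "b"))
  ds <- session_preferences(prefs)
  expect_equal(nrow(ds), 2)          # the 100-vs-100 record is uninformative
  expect_equal(ds$a, c(80, 120))
})

test_that("preference CSV and pGP JSON round-trip", {
  prefs <- data.frame(step_index = 1:3,
                      frequency_a_hz = c(80, 100, 120),
                      frequency_b_hz = c(60, 80, 100),
                      winner = c("a", "a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_preferences_csv(prefs, path)
  ds <- read_preferences_csv(path)
  expect_equal(ds$a, c(80, 100, 100))
  expect_equal(ds$b, c(60, 80, 120))

  m <- fit_pgp_map(session_preferences(prefs), kernel_params(ell = 20, signal_var = 1),
                   seed = 3)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_pgp_json(m, jpath)
  m2 <- read_pgp_json(jpath)
  grid <- seq(60, 140, 10)
  expect_equal(pgp_predict(m2, grid)$mu, pgp_predict(m, grid)$mu, tolerance = 1e-8)
  expect_equal(pgp_predict(m2, grid)$sigma, pgp_predict(m, grid)$sigma, tolerance = 1e-8)
})
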