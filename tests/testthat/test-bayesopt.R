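test_that("expected improvement matches closed-form special cases", {
  # zero posterior sd -> zero utility, regardless of mean
  pred <- predictive_distribution(c(10, 20, 30), c(1, 5, 0.2), c(0, 0.4, 0))
  u <- expected_improvement(pred, incumbent = 1)
  expect_equal(u[1], 0)
  expect_equal(u[3], 0)
  # at mu = incumbent, u = sigma * dnorm(0) = 0.398942 * sigma
  u0 <- expected_improvement(predictive_distribution(1, 2, 0.7), 2)
  expect_equal(u0, 0.398942 * 0.7, tolerance = 1e-6)
})

test_that("expected improvement agrees with Monte-Carlo E[max(incumbent - Y, 0)]", {
  set.seed(123)
  for (i in 1:5) {
    mu <- runif(1, 0, 2); sg <- runif(1, 0.05, 0.6); inc <- mu + runif(1, -0.7, 0.7)
    u <- expected_improvement(predictive_distribution(1, mu, sg), inc)
    z <- rnorm(5e5)  # antithetic pairs reduce the Monte-Carlo error
    mc <- mean((pmax(inc - (mu + sg * z), 0) + pmax(inc - (mu - sg * z), 0)) / 2)
    expect_lt(abs(u - mc), 1e-3)
  }
})

test_that("EI is monotone in sigma and in the improvement margin", {
  sigmas <- seq(0.01, 1, length.out = 50)
  u_sig <- expected_improvement(
    predictive_distribution(seq_along(sigmas), rep(1, 50), sigmas), 1.2)
  expect_true(all(diff(u_sig) > 0))
  mus <- seq(2, 0, length.out = 50)  # increasing improvement incumbent - mu
  u_mu <- expected_improvement(
    predictive_distribution(seq_along(mus), mus, rep(0.3, 50)), 1.0)
  expect_true(all(diff(u_mu) > 0))
})

test_that("next-frequency selection breaks ties low and avoids noise-free repeats", {
  grid <- seq(10, 185, by = 5)
  kp <- kernel_params(ell = 30, signal_var = 1, noise_var = 0)
  # prior-only model: utility constant -> lowest grid frequency
  sel0 <- select_next_frequency(gp_model(kp, mean_const = 1), grid)
  expect_equal(sel0$x_next, 10)
  expect_false(sel0$overexploit_flag)
  # noise-free training points have zero EI, so the proposal is elsewhere
  obs <- observation_set(c(40, 90, 150), c(2, 1.5, 0.5))
  sel <- select_next_frequency(gp_model(kp, obs), grid)
  expect_false(sel$x_next %in% obs$frequency_hz)
  expect_true(all(sel$utility >= 0))
  # ceiling restricts the feasible grid
  selc <- select_next_frequency(gp_model(kp, obs), grid, ceiling = 100)
  expect_lte(selc$x_next, 100)
  expect_error(select_next_frequency(gp_model(kp, obs), grid, ceiling = 5),
               class = "dbstune_no_feasible_frequency")
})

test_that("over-exploitation triggers the maximum-variance override", {
  # huge noise floor: any sigma is below exploration_ratio * sqrt(noise_var)
  kp <- kernel_params(ell = 30, signal_var = 1, noise_var = 100)
  obs <- observation_set(c(40, 150), c(2, 0.5))
  grid <- seq(10, 185, by = 5)
  sel <- select_next_frequency(gp_model(kp, obs), grid)
  expect_true(sel$overexploit_flag)
  pred <- gp_predict(gp_model(kp, obs), grid)
  expect_equal(sel$x_next, grid[which.max(pred$sigma)])
})

test_that("brute-force schedule has the protocol's counts and determinism", {
  s36 <- brute_force_schedule(10, 185, 5, clinical_freq = 125, seed = 4)
  expect_equal(length(unique(setdiff(s36, 125))) + 1, 36)  # 36 grid settings
  expect_equal(length(s36), 38)                            # + 2 clinical repeats
  expect_equal(s36[1], 125)
  expect_equal(s36[length(s36)], 125)
  expect_equal(length(unique(brute_force_schedule(10, 155, 5))), 30)
  expect_identical(brute_force_schedule(seed = 7), brute_force_schedule(seed = 7))
  expect_false(identical(brute_force_schedule(seed = 7), brute_force_schedule(seed = 8)))
  expect_error(brute_force_schedule(100, 50), class = "dbstune_invalid_parameter")
  expect_error(brute_force_schedule(10, 185, 8), class = "dbstune_invalid_parameter")
})

test_that("a full session yields 12 measurements, 11 preferences, deterministically", {
  patient <- virtual_patient("ar1")
  cfg <- session_config(rng_seed = 101, fmax = 155)
  s1 <- run_session(patient, cfg)
  expect_equal(nrow(s1$history), 12)
  expect_equal(nrow(s1$preferences), 11)
  expect_equal(sum(s1$history$source == "seed"), 4)
  expect_equal(s1$history$frequency_hz[1:4], c(30, 80, 90, 140))
  expect_equal(s1$mean_const, mean(s1$history$romar[1:4]))
  s2 <- run_session(patient, cfg)
  expect_identical(s1$history, s2$history)
  expect_identical(s1$preferences, s2$preferences)
  # preferences off: measurements only
  s3 <- run_session(patient, session_config(rng_seed = 101, fmax = 155,
                                            preference_enabled = FALSE))
  expect_equal(nrow(s3$preferences), 0)
  expect_equal(nrow(s3$history), 12)
})

test_that("an intolerable frequency lowers the ceiling for the rest of the session", {
  # patient tolerates only up to 120 Hz but the session grid runs to 185;
  # the 140 Hz seed is intolerable, so only 3 seeds yield measurements
  patient <- virtual_patient("ar1", ceiling = 120)
  s <- run_session(patient, session_config(rng_seed = 5))
  expect_equal(nrow(s$history), 3 + 8)
  expect_equal(nrow(s$preferences), 3 + 8 - 1)
  expect_true(all(s$history$frequency_hz <= 120))
  expect_lte(s$ceiling, 120)
  # a ceiling declared up front restricts the grid without losing seeds
  s2 <- run_session(virtual_patient("ar1", ceiling = 120),
                    session_config(rng_seed = 5, seeds = c(30, 80, 90, 110)))
  expect_equal(nrow(s2$history), 12)
})
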