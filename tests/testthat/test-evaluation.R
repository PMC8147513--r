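test_that("optimal frequency is the posterior-mean argmin with low tie-break", {
  grid <- seq(10, 155, by = 5)
  dec <- predictive_distribution(grid, seq(2, 0.5, length.out = length(grid)),
                                 rep(0.1, length(grid)))
  expect_equal(optimal_frequency(dec), 155)
  flat <- predictive_distribution(grid, rep(1, length(grid)), rep(0.1, length(grid)))
  expect_equal(optimal_frequency(flat), 10)
  # fitted GP on a dense noiseless sample finds the true argmin
  p <- virtual_patient("ar1", noise_sd = 0)
  obs <- observation_set(grid, true_rigidity(p, grid))
  fit <- fit_hyperparameters(obs, seed = 1)
  pred <- gp_predict(gp_model(fit, obs), grid)
  expect_lte(abs(optimal_frequency(pred) - 155), 5)
})

test_that("frequency range computes the one-sigma set, width, and lower distance", {
  # hand-built V: mu = 3,2,1,2,3 with sigma_min = 1 -> middle three qualify
  pred <- predictive_distribution(c(10, 15, 20, 25, 30), c(3, 2, 1, 2, 3), rep(1, 5))
  fr <- frequency_range(pred)
  expect_equal(fr$x_opt, 20)
  expect_equal(fr$range_set, c(15, 20, 25))
  expect_equal(fr$interval, c(15, 25))
  expect_equal(fr$width, 10)          # two grid steps
  expect_equal(fr$lower_distance, 5)
  # constant mu, positive sigma: whole grid qualifies
  grid <- seq(10, 185, by = 5)
  frc <- frequency_range(predictive_distribution(grid, rep(1, 36), rep(0.2, 36)))
  expect_equal(frc$width, 175)
  expect_equal(frc$range_set, grid)
  # V-shaped mean with vanishing sigma: width collapses to zero
  frv <- frequency_range(predictive_distribution(
    c(10, 15, 20, 25, 30), c(3, 2, 1, 2, 3), rep(1e-12, 5)))
  expect_equal(frv$width, 0)
  expect_equal(frv$lower_distance, 0)
})

test_that("shrinking sigma never widens the frequency range", {
  set.seed(21)
  grid <- seq(10, 185, by = 5)
  for (rep in 1:10) {
    mu <- as.numeric(stats::filter(rnorm(36), rep(1 / 5, 5), circular = TRUE))
    sg <- runif(36, 0.05, 0.5)
    w1 <- frequency_range(predictive_distribution(grid, mu, sg))$width
    for (c_ in c(0.7, 0.3)) {
      w2 <- frequency_range(predictive_distribution(grid, mu, c_ * sg))$width
      expect_lte(w2, w1)
    }
  }
})

test_that("equal-interval selection matches the protocol's worked example", {
  p <- virtual_patient("ar1")
  bf <- run_brute_force(p, fmax = 155, seed = 3)
  ei3 <- simulate_equal_interval(bf, 3, seed = 1)
  expect_equal(attr(ei3, "selected"), c(10, 85, 155))  # 3 points to a 155 Hz ceiling
  ei2 <- simulate_equal_interval(bf, 2, seed = 1)
  expect_equal(attr(ei2, "selected"), c(10, 155))
  expect_error(simulate_equal_interval(bf, 1), class = "dbstune_invalid_parameter")
  # saturation: selecting every tested frequency equals the full fit
  n_all <- length(unique(bf$frequency_hz))
  ei_all <- simulate_equal_interval(bf, n_all, seed = 5)
  full <- frequency_range(gp_predict(
    gp_model(fit_hyperparameters(pick_obs_for_test(bf), seed = 5),
             pick_obs_for_test(bf)),
    sort(unique(bf$frequency_hz))))
  expect_equal(ei_all$width, full$width, tolerance = 1e-9)
  expect_equal(ei_all$x_opt, full$x_opt)
})

test_that("random subsampling is seeded, reports sd, and tightens with n", {
  p <- virtual_patient("ar1")
  bf <- run_brute_force(p, fmax = 155, seed = 3)
  r1 <- simulate_random(bf, 6, reps = 5, seed = 11)
  r2 <- simulate_random(bf, 6, reps = 5, seed = 11)
  expect_identical(r1, r2)
  expect_equal(simulate_random(bf, 6, reps = 1, seed = 2)$sd_width, 0)
  # widths trend down toward the full-data width as n grows
  widths <- vapply(c(3, 6, 12, 24), function(n)
    simulate_random(bf, n, reps = 8, seed = 4)$mean_width, 0)
  full_w <- simulate_equal_interval(bf, length(unique(bf$frequency_hz)), seed = 4)$width
  expect_lt(widths[4], widths[1])
  expect_lte(abs(widths[4] - full_w), 30)  # near the brute-force width by n = 24
})

test_that("the efficiency report has the protocol's layout", {
  p <- virtual_patient("ar1")
  s <- run_session(p, session_config(rng_seed = 31, fmax = 155))
  bf <- run_brute_force(p, fmax = 155, seed = 31)
  rep_tbl <- efficiency_report(bf = bf, session = s, n_values = c(3, 6),
                               reps = 3, seed = 31)
  expect_equal(sum(rep_tbl$method == "bayesopt"), nrow(s$history))
  expect_equal(sum(rep_tbl$method == "equal_interval"), 2)
  expect_equal(sum(rep_tbl$method == "random"), 6)
  expect_true(all(c("method", "n", "rep", "width_hz", "lower_distance_hz",
                    "x_opt_hz") %in% names(rep_tbl)))
  # widths defined from the second measurement onward
  bo <- rep_tbl[rep_tbl$method == "bayesopt", ]
  expect_true(is.na(bo$width_hz[1]))
  expect_true(all(!is.na(bo$width_hz[bo$n >= 2])))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(rep_tbl, path)
  expect_equal(nrow(read.csv(path)), nrow(rep_tbl))
})

test_that("brute-force runs respect the patient's tolerability ceiling", {
  p <- virtual_patient("ar1")  # ceiling 155, grid to 185
  bf <- run_brute_force(p, fmax = 185, clinical_freq = 125, seed = 6)
  expect_true(all(bf$frequency_hz <= 155))
  expect_equal(sum(bf$source == "clinical_repeat"), 2)
  expect_equal(length(unique(bf$frequency_hz)), 30)  # 10..155 by 5
  # noiseless strictly decreasing curve: optimum at the ceiling
  p0 <- virtual_patient("ar1", noise_sd = 0)
  bf0 <- run_brute_force(p0, fmax = 155, seed = 6)
  fr <- simulate_equal_interval(bf0, length(unique(bf0$frequency_hz)), seed = 1)
  expect_equal(fr$x_opt, 155)
})
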