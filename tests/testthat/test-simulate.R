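test_that("simulate_ewe is deterministic and respects the fix schedule", {
  cfg <- sim_config(seed = 11)
  a <- simulate_ewe(cfg)
  b <- simulate_ewe(cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$truth, b$truth)
  dt <- diff(as.numeric(a$trajectory$timestamp))
  expect_true(all(dt == 7200))
  expect_equal(nrow(a$trajectory),
               as.integer(difftime(cfg$season_end, cfg$season_start,
                                   units = "hours")) / 2 + 1)
})

test_that("the parturition bout forces non-movement and drives the daily step minimum", {
  ev <- as.POSIXct("2022-06-04 00:00:00", tz = "UTC")  # day 20 of the season
  cfg <- sim_config(seed = 1, event_time = ev)
  sim <- simulate_ewe(cfg)
  in_bout <- sim$truth$timestamp >= ev &
    sim$truth$timestamp < ev + cfg$bout_duration * 3600
  expect_true(all(sim$truth$true_state[in_bout] == "non-movement"))
  # daily average step length is minimized inside the bout window
  d <- step_lengths(sim$trajectory)
  day <- as.Date(sim$trajectory$timestamp)
  daily <- tapply(d[-length(d)], day[-length(d)], mean)
  argmin_day <- as.Date(names(daily)[which.min(daily)])
  expect_true(argmin_day >= as.Date(ev) &
                argmin_day <= as.Date(ev + cfg$bout_duration * 3600))
})

test_that("non-parturient simulations carry no event and no forced bout", {
  sim <- simulate_ewe(sim_config(parturient = FALSE, seed = 3))
  expect_null(sim$event_time)
  # non-movement occurs only through the background chain: no 24-fix run
  r <- rle(as.character(sim$truth$true_state))
  nm_runs <- r$lengths[r$values == "non-movement"]
  expect_true(length(nm_runs) == 0 || max(nm_runs) < 24)
})

test_that("empirical step-length means recover the configured regime ordering", {
  # boost non-movement occupancy so every regime has >= 500 fixes
  tm <- matrix(c(0.85, 0.10, 0.05,
                 0.10, 0.75, 0.15,
                 0.05, 0.15, 0.80), 3, 3, byrow = TRUE)
  cfg <- sim_config(transition_matrix = tm, parturient = FALSE, seed = 7,
                    season_start = as.POSIXct("2022-04-01", tz = "UTC"),
                    season_end = as.POSIXct("2022-09-01", tz = "UTC"))
  sim <- simulate_ewe(cfg)
  st <- as.character(sim$truth$true_state)[-nrow(sim$trajectory)]
  d <- step_lengths(sim$trajectory)[-nrow(sim$trajectory)]
  m <- tapply(d, st, mean)
  n <- tapply(d, st, length)
  expect_true(all(n >= 500))
  expect_lt(m[["non-movement"]], m[["low-movement"]])
  expect_lt(m[["low-movement"]], m[["high-movement"]])
})

test_that("configuration invariants are enforced", {
  bad_tm <- matrix(1 / 3, 3, 3); bad_tm[1, 1] <- 0.5
  expect_error(sim_config(transition_matrix = bad_tm), "row-stochastic")
  expect_error(sim_config(step_mean = c(150, 30, 600)), "ordered")
  expect_error(sim_config(p_spike = 0.3), "error rates")
  expect_error(sim_config(bout_duration = -1), "bout_duration")
  expect_error(
    simulate_ewe(sim_config(event_time = as.POSIXct("2022-08-01", tz = "UTC"),
                            seed = 1)),
    "inside the season")
})

test_that("error injection: zero rates are the identity, spikes carry the rule-3 signature", {
  sim <- simulate_ewe(sim_config(seed = 21, parturient = FALSE))
  expect_identical(inject_gps_errors(sim, p_2d = 0, p_spike = 0), sim)

  noisy <- inject_gps_errors(sim, p_2d = 0, p_spike = 0.02, seed = 22)
  spikes <- which(noisy$truth$error_flag)
  expect_gt(length(spikes), 0)
  k <- fix_kinematics(noisy$trajectory)
  expect_true(all(k$incoming_speed[spikes] > 2))
  expect_true(all(k$outgoing_speed[spikes] > 2))
  expect_true(all(k$turn_cosine[spikes] < -0.97))
})

test_that("injected 2D flags match an independent RNG replay", {
  sim <- simulate_ewe(sim_config(seed = 31, parturient = FALSE))
  n <- nrow(sim$trajectory)
  noisy <- inject_gps_errors(sim, p_2d = 0.01, p_spike = 0, seed = 33)
  set.seed(33)
  expected <- runif(n) < 0.01
  expect_identical(noisy$trajectory$fix_class == "2D", expected)
  expect_identical(noisy$truth$error_flag, expected)
})
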