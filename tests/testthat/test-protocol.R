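test_that("identical seeds give bit-identical logs", {
  proto <- cycle_protocol(setpoint = 37, n_cycles = 1)
  a <- run_protocol(proto, seed = 5, noise_sd = 0.2)
  b <- run_protocol(proto, seed = 5, noise_sd = 0.2)
  expect_identical(a, b)
  c <- run_protocol(proto, seed = 6, noise_sd = 0.2)
  expect_false(identical(a$t_dish_c, c$t_dish_c))
})

test_that("set point at ambient keeps the log flat with near-zero duty", {
  pl <- plant_params()
  proto <- cycle_protocol(setpoint = pl$t_amb, n_cycles = 1, heat_hold = 60,
                          cool_hold = 10)
  log <- run_protocol(proto, plant = pl, noise_sd = 0)
  expect_lt(max(abs(log$t_dish_c - pl$t_amb)), 0.5)
  expect_lt(max(abs(log$t_block_c - pl$t_amb)), 0.5)
  expect_lt(max(log$duty), 0.05)
})

test_that("block leads dish on heating and both decay on cooling", {
  log <- run_protocol(cycle_protocol(setpoint = 37, n_cycles = 1))
  heat <- log[log$setpoint_c == 37, ]
  rising <- heat[heat$t_dish_c < 36, ]
  expect_true(mean(rising$t_block_c > rising$t_dish_c) > 0.95)
  cool <- log[log$setpoint_c != 37, ]
  n <- nrow(cool)
  expect_lt(cool$t_dish_c[n], cool$t_dish_c[1])
  expect_lt(cool$t_block_c[n], cool$t_block_c[1])
  expect_true(all(cool$duty == 0))
})

test_that("latency matches the first-order closed-form crossing time", {
  log <- exp_approach_log(t_amb = 20, delta = 17, tau = 120, setpoint = 37)
  res <- measure_latency(log, channel = "dish", direction = "heating",
                         band = 0.5, dwell = 0)
  expect_equal(res$per_cycle[1], 120 * log(17 / 0.5), tolerance = 2 / 423)
})

test_that("a log already inside the band has zero latency", {
  tt <- 0:100
  log <- temperature_log(data.frame(time_s = tt, t_dish_c = 37,
                                    t_block_c = 37, duty = 0.5,
                                    setpoint_c = 37))
  expect_equal(measure_latency(log, "dish", "heating")$per_cycle[1], 0)
})

test_that("dwell requirement rejects transient band entries", {
  # touches the band for 3 s, leaves, then settles for good
  temp <- c(seq(20, 36.6, length.out = 50), rep(36.6, 3), rep(35, 20),
            rep(36.8, 60))
  tt <- seq_along(temp) - 1
  log <- temperature_log(data.frame(time_s = tt, t_dish_c = temp,
                                    t_block_c = temp, duty = 1,
                                    setpoint_c = 37))
  quick <- measure_latency(log, "dish", "heating", band = 0.5, dwell = 0)
  patient <- measure_latency(log, "dish", "heating", band = 0.5, dwell = 10)
  expect_lt(quick$per_cycle[1], patient$per_cycle[1])
  expect_equal(patient$per_cycle[1], 73)
})

test_that("unreachable set point raises a non-convergence error", {
  proto <- cycle_protocol(setpoint = 80, n_cycles = 1)
  expect_error(run_protocol(proto, max_phase_s = 300),
               "tolerance band|equilibrium")
})

test_that("a channel that never reaches the band is flagged not reached", {
  log <- exp_approach_log(t_amb = 20, delta = 10, tau = 120, setpoint = 37,
                          t_end = 600)
  res <- measure_latency(log, "dish", "heating")
  expect_true(is.na(res$per_cycle[1]))
  expect_false(res$reached[1])
})

test_that("log statistics match hand-computed values", {
  tt <- 0:99
  log <- temperature_log(data.frame(time_s = tt, t_dish_c = 37,
                                    t_block_c = 37, duty = 0,
                                    setpoint_c = 37))
  s <- log_stats(log, "dish")
  expect_equal(s$mean, 37)
  expect_equal(s$sd, 0)
  expect_equal(s$range, 0)
  expect_equal(s$iqr, 0)

  log2 <- temperature_log(data.frame(time_s = 0:3, t_dish_c = c(1, 2, 3, 4),
                                     t_block_c = 0, duty = 0, setpoint_c = 1))
  s2 <- log_stats(log2, "dish", window = c(0, 3))
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$sd, 1.2909944, tolerance = 1e-6)
  expect_equal(s2$iqr, 1.5)
})

test_that("log_stats equals a brute-force recomputation on random logs", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    temp <- 30 + cumsum(rnorm(n, sd = 0.3))
    log <- temperature_log(data.frame(time_s = seq_len(n), t_dish_c = temp,
                                      t_block_c = temp, duty = 0,
                                      setpoint_c = 37))
    w <- sort(sample(seq_len(n), 2))
    s <- log_stats(log, "dish", window = c(w[1], w[2]))
    x <- temp[w[1]:w[2]]
    m <- sum(x) / length(x)
    expect_equal(s$mean, m)
    if (length(x) > 1)
      expect_equal(s$sd, sqrt(sum((x - m)^2) / (length(x) - 1)))
    expect_equal(s$range, max(x) - min(x))
    qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    expect_equal(s$iqr, qs[2] - qs[1])
  }
})

test_that("empty analysis windows raise explicit errors", {
  log <- exp_approach_log(t_end = 100)
  expect_error(log_stats(log, "dish", window = c(500, 600)), "empty")
  expect_error(log_stats(log, "dish", window = "after-first-reach"),
               "never entered")
})

test_that("an hour-long hold at 37 keeps the dish in a narrow band", {
  log <- run_hold(37, 3600, noise_sd = 0.15, seed = 7)
  s <- log_stats(log, "dish", window = "after-first-reach", band = 0.5)
  expect_lt(abs(s$mean - 37), 1)
  expect_lt(s$range, 2.5)
  expect_lt(s$sd, 0.5)
})
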