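test_that("generators are pure functions of their seed", {
  cfg <- trace_gen_config(n_cells = 5, duration_s = 60, seed = 17)
  a <- gen_traces(cfg)
  b <- gen_traces(cfg)
  expect_identical(a, b)
  set.seed(123); before <- runif(1)
  set.seed(123); gen_traces(cfg); after <- runif(1)
  expect_identical(before, after)  # global RNG untouched

  ma <- gen_label_mask(4, "ellipse", seed = 9)
  mb <- gen_label_mask(4, "ellipse", seed = 9)
  expect_identical(ma, mb)
})

test_that("zero event rate and zero noise give the bare bleaching baseline", {
  cfg <- trace_gen_config(n_cells = 3, duration_s = 120, event_rate = 0,
                          noise_sd = 0, bleach_slope = 0.05, seed = 1)
  out <- gen_traces(cfg)
  expect_equal(nrow(out$ground_truth), 0L)
  tt <- (seq_len(600) - 1) / 5
  expected <- 100 * exp(-0.05 * tt / 60)
  expect_equal(out$traces[[1]]$values, expected)
  for (tr in out$traces)
    expect_equal(nrow(analyze_trace(tr)), 0L)
})

test_that("injected event counts match the nominal mean within 3 sqrt(mean)", {
  cfg <- trace_gen_config(n_cells = 100, duration_s = 180, event_rate = 1,
                          seed = 31)
  gt <- gen_traces(cfg)$ground_truth
  lambda <- 100 * 3  # cells x minutes x rate
  expect_lt(abs(nrow(gt) - lambda), 3 * sqrt(lambda))
  # refractory gap respected within every cell
  for (i in unique(gt$cell_id)) {
    on <- gt$onset_s[gt$cell_id == i]
    if (length(on) > 1) expect_true(all(diff(on) >= 10))
  }
})

test_that("nominal width formula matches a fine-grid evaluation of the kernel", {
  for (amp in c(0.6, 0.8, 1.0, 1.3)) {
    tt <- seq(0, 40, by = 1e-4)
    kern <- amp * ifelse(tt <= 0.5, tt / 0.5, exp(-(tt - 0.5) / 5))
    grid_width <- sum(kern > 0.5) * 1e-4
    expect_equal(nominal_event_width(amp), grid_width, tolerance = 1e-3)
  }
  expect_equal(nominal_event_width(0.4), 0)
})

test_that("label masks respect counts, labelling and analytic geometry", {
  empty <- gen_label_mask(0, "circle")
  expect_true(all(empty$mask == 0L))

  m <- gen_label_mask(6, "circle", size_range = c(10, 24),
                      image_size = c(300, 300), seed = 5)
  labs <- sort(unique(as.integer(m$mask[m$mask > 0])))
  expect_identical(labs, 1:6)
  for (i in 1:6) {
    measured <- sum(m$mask == i)
    expect_equal(measured, m$truth$area[i], tolerance = 0.02)
  }

  me <- gen_label_mask(3, "ellipse", size_range = c(14, 20),
                       image_size = c(256, 256), seed = 8)
  rec <- measure_regions(me$mask)
  expect_equal(rec$area_px, me$truth$area, tolerance = 0.04)
  expect_equal(rec$perimeter_px, me$truth$perimeter, tolerance = 0.05)

  expect_error(gen_label_mask(500, "circle", size_range = c(30, 40),
                              image_size = c(128, 128), seed = 1,
                              max_tries = 600),
               "could not place")
})

test_that("movies round-trip through extraction and average noise as 1/sqrt(m)", {
  mk <- gen_label_mask(3, "circle", size_range = c(10, 14),
                       image_size = c(120, 120), seed = 12)
  cfg <- trace_gen_config(n_cells = 3, duration_s = 10, fs = 2, seed = 3)
  traces <- gen_traces(cfg)$traces
  stack <- gen_movie(traces, mk$mask, background = 10, noise_sd = 0)
  rec <- extract_traces(stack, mk$mask, fs = 2)
  for (i in 1:3)
    expect_equal(rec[[as.character(i)]]$values, traces[[i]]$values)

  # constant traces + pixel noise: recovered sd ~ sigma / sqrt(region size)
  flat <- lapply(1:3, function(i) fluor_trace(rep(50, 200), 2, i))
  noisy <- gen_movie(flat, mk$mask, background = 10, noise_sd = 4, seed = 21)
  rec_n <- extract_traces(noisy, mk$mask, fs = 2)
  for (i in 1:3) {
    m_px <- sum(mk$mask == i)
    expect_equal(sd(rec_n[[as.character(i)]]$values), 4 / sqrt(m_px),
                 tolerance = 0.25)
  }

  expect_error(gen_movie(traces[1:2], mk$mask), "one-to-one")
})

test_that("full pipeline recovers the injected event rate on a cohort", {
  cfg <- trace_gen_config(n_cells = 100, duration_s = 180, fs = 5,
                          event_rate = 1, seed = 47)
  out <- gen_traces(cfg)
  kin <- summarize_cells(out$traces)
  total_min <- 100 * 3
  injected <- nrow(out$ground_truth)
  se <- sqrt(injected) / total_min
  expect_lt(abs(mean(kin$freq_per_min) - 1.0), 2 * se + 1e-12)
})
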