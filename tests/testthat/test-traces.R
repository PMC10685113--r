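test_that("baseline of a constant trace is that constant and ignores short plateaus", {
  fs <- 5
  tr <- fluor_trace(rep(100, 300), fs = fs)
  cfg <- detector_config(baseline_window_s = 30, baseline_percentile = 10)
  expect_equal(estimate_baseline(tr, cfg), rep(100, 300))

  # 10 s plateau at 180 inside a 100-baseline trace, window 3x the plateau
  v <- rep(100, 60 * fs)
  v[101:150] <- 180
  f0 <- estimate_baseline(fluor_trace(v, fs = fs), cfg)
  expect_lt(max(f0[101:150]), 101)
})

test_that("adding a transient never lowers the rolling-percentile baseline", {
  fs <- 5
  set.seed(2)
  base <- 100 + rnorm(300, sd = 2)
  v2 <- base
  v2[120:140] <- v2[120:140] + 80
  cfg <- detector_config()
  f0a <- estimate_baseline(fluor_trace(base, fs = fs), cfg)
  f0b <- estimate_baseline(fluor_trace(v2, fs = fs), cfg)
  expect_true(all(f0b >= f0a - 1e-9))
})

test_that("baseline rejects degenerate inputs", {
  expect_error(estimate_baseline(fluor_trace(rep(0, 100), 5)), "all-zero")
  expect_error(estimate_baseline(fluor_trace(rep(1, 10), 5),
                                 detector_config(baseline_window_s = 30)),
               "shorter")
})

test_that("delta-F/F is exact arithmetic and cancels detector gain", {
  fs <- 5
  v <- rep(100, 100); v[40:60] <- 180
  tr <- fluor_trace(v, fs)
  d <- compute_dff(tr, rep(100, 100))
  expect_equal(d$dff[1], 0)
  expect_equal(d$dff[50], 0.8)

  g <- 7.3
  d_gain <- compute_dff(fluor_trace(g * v, fs), rep(g * 100, 100))
  expect_equal(d_gain$dff, d$dff)

  expect_error(compute_dff(tr, rep(0, 100)), "positive")
  expect_error(compute_dff(tr, rep(100, 50)), "length")
})

test_that("moving-average denoising is exact on spikes and contracts variance", {
  fs <- 5
  d <- dff_from(rep(0.2, 100), fs)
  expect_equal(denoise(d, detector_config(smoothing_window_s = 1))$dff,
               rep(0.2, 100))

  spike <- dff_from(c(rep(0, 50), 1, rep(0, 50)), fs)
  w <- 5L  # 1 s at 5 Hz
  sm <- denoise(spike, detector_config(smoothing_window_s = 1))
  expect_equal(max(sm$dff), 1 / w)

  set.seed(9)
  noisy <- dff_from(rnorm(500), fs)
  expect_lt(var(denoise(noisy, detector_config())$dff), var(noisy$dff))

  expect_error(denoise(dff_from(rep(0, 3), fs),
                       detector_config(smoothing_window_s = 10)), "longer")
})

test_that("the width and height criteria are individually enforced", {
  fs <- 5
  mk <- function(h, dur_s) {
    v <- rep(0, 20 * fs)
    v[(5 * fs + 1):(5 * fs + dur_s * fs)] <- h
    dff_from(v, fs)
  }
  ev <- detect_transients(mk(0.6, 3))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$width_s, 3)
  expect_equal(ev$height, 0.6)
  expect_equal(ev$auc, 0.6 * 3)

  expect_equal(nrow(detect_transients(mk(0.6, 1))), 0L)   # too short
  expect_equal(nrow(detect_transients(mk(0.4, 10))), 0L)  # too low
  expect_equal(nrow(detect_transients(mk(0.6, 2))), 1L)   # exactly 2 s kept
})

test_that("a triangular pulse yields the piecewise-linear width and AUC", {
  fs <- 20
  tt <- seq(0, 6, by = 1 / fs)
  v <- pmax(0, ifelse(tt <= 2, tt / 2, (4 - tt) / 2))
  ev <- detect_transients(dff_from(v, fs))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$width_s, 2, tolerance = 0.06)
  expect_equal(ev$auc, 1.5, tolerance = 0.05)
})

test_that("detector equals the brute-force segment oracle on random traces", {
  set.seed(33)
  fs <- 5
  for (rep in 1:1000) {
    x <- rnorm(60, mean = 0.3, sd = 0.4)
    thr <- runif(1, 0.2, 0.8)
    mw <- sample(c(0.4, 1, 2), 1)
    ev <- detect_transients(dff_from(x, fs),
                            detector_config(height_threshold = thr,
                                            min_width_s = mw))
    oracle <- brute_force_events(x, fs, thr, mw)
    expect_equal(nrow(ev), nrow(oracle))
    if (nrow(ev)) {
      expect_equal(ev$start_s, (oracle$start - 1) / fs)
      expect_equal(ev$width_s, (oracle$end - oracle$start + 1) / fs)
      expect_equal(ev$height, vapply(seq_len(nrow(oracle)), function(i)
        max(x[oracle$start[i]:oracle$end[i]]), numeric(1)))
    }
  }
})

test_that("raising either threshold never increases the event count", {
  set.seed(14)
  fs <- 5
  for (rep in 1:30) {
    x <- abs(rnorm(200, mean = 0.4, sd = 0.5))
    n_base <- nrow(detect_transients(dff_from(x, fs),
                                     detector_config(0.5, 2)))
    expect_lte(nrow(detect_transients(dff_from(x, fs),
                                      detector_config(0.7, 2))), n_base)
    expect_lte(nrow(detect_transients(dff_from(x, fs),
                                      detector_config(0.5, 3))), n_base)
  }
})

test_that("every event satisfies the AUC lower bound", {
  set.seed(15)
  fs <- 5
  for (rep in 1:50) {
    x <- abs(rnorm(300, mean = 0.4, sd = 0.5))
    ev <- detect_transients(dff_from(x, fs))
    if (nrow(ev))
      expect_true(all(ev$auc >= 0.5 * ev$width_s - 1e-12))
  }
})

test_that("the end-to-end pipeline is invariant to detector gain", {
  cfg_gen <- trace_gen_config(n_cells = 5, duration_s = 120, seed = 71)
  traces <- gen_traces(cfg_gen)$traces
  for (tr in traces) {
    ev1 <- analyze_trace(tr)
    tr2 <- fluor_trace(13.7 * tr$values, tr$fs, tr$cell_id)
    ev2 <- analyze_trace(tr2)
    expect_equal(ev1$start_s, ev2$start_s)
    expect_equal(ev1$width_s, ev2$width_s)
    expect_equal(ev1$height, ev2$height, tolerance = 1e-9)
  }
})

test_that("cell summaries encode frequency and the activity rule", {
  ev <- data.frame(cell_id = 1, start_s = c(10, 60, 110),
                   end_s = c(14, 64, 114), width_s = 4, height = 1, auc = 4)
  k <- summarize_cell(ev, duration_s = 180)
  expect_equal(k$freq_per_min, 1.0)
  expect_true(k$active)
  expect_equal(k$mean_width_s, 4)

  k0 <- summarize_cell(ev[0, ], duration_s = 180, cell_id = 9)
  expect_false(k0$active)
  expect_equal(k0$freq_per_min, 0)
  expect_true(is.na(k0$mean_width_s))
  expect_error(summarize_cell(ev, duration_s = -1), "duration")
})

test_that("trace extraction recovers painted traces and ignores background", {
  mask <- matrix(0L, 20, 20)
  mask[2:6, 2:6] <- 1L
  mask[10:15, 10:18] <- 2L
  v1 <- c(10, 20, 30, 40)
  v2 <- c(5, 5, 80, 5)
  stack <- gen_movie(list(fluor_trace(v1, 5, 1L), fluor_trace(v2, 5, 2L)),
                     mask, background = 3)
  out <- extract_traces(stack, mask, fs = 5)
  expect_length(out, 2L)
  expect_equal(out[["1"]]$values, v1)
  expect_equal(out[["2"]]$values, v2)

  uni <- array(7, dim = c(20, 20, 3))
  out_u <- extract_traces(uni, mask, fs = 5)
  expect_equal(out_u[["1"]]$values, rep(7, 3))

  expect_identical(extract_traces(uni, matrix(0L, 20, 20)), list())
  expect_error(extract_traces(uni, matrix(0L, 5, 5)), "dimensions")
})
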