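# Independent oracles and small fixture builders shared across tests.

# Build a dff_trace directly from delta-F/F values (bypasses baselining).
dff_from <- function(values, fs = 5, cell_id = 1L) {
  structure(list(cell_id = cell_id, fs = fs, dff = as.numeric(values),
                 baseline = rep(1, length(values))),
            class = "dff_trace")
}

# Brute-force transient oracle: scan every sample, grow each contiguous
# above-threshold segment explicitly, keep those meeting the width rule.
brute_force_events <- function(x, fs, thr, min_width_s) {
  out <- data.frame(start = integer(0), end = integer(0))
  i <- 1L
  n <- length(x)
  while (i <= n) {
    if (x[i] >= thr) {
      j <- i
      while (j < n && x[j + 1L] >= thr) j <- j + 1L
      if ((j - i + 1L) / fs >= min_width_s)
        out <- rbind(out, data.frame(start = i, end = j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Hand/closed-form Welch t statistic and two-sided p.
welch_oracle <- function(a, b) {
  v1 <- sum((a - mean(a))^2) / (length(a) - 1)
  v2 <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- v1 / length(a) + v2 / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (length(a)^2 * (length(a) - 1)) +
                   v2^2 / (length(b)^2 * (length(b) - 1)))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df))
}

# Exact Mann-Whitney p by full enumeration of group assignments.
mwu_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- u_stat(seq_len(n1))
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_stat)
  # two-sided: double the smaller tail, capped at 1
  p <- 2 * min(mean(us <= obs), mean(us >= obs))
  list(u = obs, p_value = min(1, p))
}

# Permutation p-value for the slope difference of two regressions.
slope_perm_oracle <- function(x1, y1, x2, y2, B = 2000, seed = 99) {
  set.seed(seed)
  slope <- function(x, y) stats::cov(x, y) / stats::var(x)
  obs <- abs(slope(x1, y1) - slope(x2, y2))
  x <- c(x1, x2); y <- c(y1, y2)
  n1 <- length(x1)
  cnt <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(length(x), n1)
    d <- abs(slope(x[idx], y[idx]) - slope(x[-idx], y[-idx]))
    if (d >= obs) cnt <- cnt + 1L
  }
  (cnt + 1) / (B + 1)
}

# Analytic above-threshold AUC of the rise/decay event kernel.
nominal_event_auc <- function(amplitude, rise_s = 0.5, decay_tau_s = 5,
                              threshold = 0.5) {
  t1 <- rise_s * threshold / amplitude
  rise_part <- amplitude / (2 * rise_s) * (rise_s^2 - t1^2)
  decay_part <- decay_tau_s * (amplitude - threshold)
  ifelse(amplitude <= threshold, 0, rise_part + decay_part)
}

# First-order exponential approach log used for closed-form latency checks.
exp_approach_log <- function(t_amb = 20, delta = 17, tau = 120, setpoint = 37,
                             dt = 1, t_end = 1200) {
  tt <- seq(0, t_end, by = dt)
  temp <- t_amb + delta * (1 - exp(-tt / tau))
  temperature_log(data.frame(time_s = tt, t_dish_c = temp, t_block_c = temp,
                             duty = 1, setpoint_c = setpoint))
}
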