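#' Construct a temperature log
#'
#' A temperature log is a data frame with one row per sample and columns
#' `time_s`, `t_dish_c`, `t_block_c`, `duty`, `setpoint_c`. Produced by
#' [run_protocol()] or read from CSV with [read_temperature_log()].
#'
#' @param df A data frame containing at least the five standard columns.
#' @return The validated log, classed `temperature_log`.
#' @export
temperature_log <- function(df) {
  needed <- c("time_s", "t_dish_c", "t_block_c", "duty", "setpoint_c")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("temperature_log: missing columns: ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[, needed]
  if (nrow(df) == 0) stop("temperature_log: empty log")
  if (any(diff(df$time_s) <= 0))
    stop("temperature_log: 'time_s' must be strictly increasing")
  class(df) <- c("temperature_log", "data.frame")
  df
}

#' Thermal cycling protocol
#'
#' Defines one or more heat/hold/cool/hold cycles between ambient and a
#' set point, mirroring the cycling used to characterise the controller.
#'
#' @param setpoint Target temperature (degree C).
#' @param n_cycles Number of cycles (>= 1).
#' @param heat_hold Dwell at set point after reaching it (s).
#' @param cool_hold Dwell at ambient after cooling back (s).
#' @param tolerance_band Half-width of the "reached" band (degree C, > 0).
#' @return An object of class `cycle_protocol`.
#' @export
cycle_protocol <- function(setpoint = 37, n_cycles = 3, heat_hold = 120,
                           cool_hold = 60, tolerance_band = 0.5) {
  if (n_cycles < 1) stop("cycle_protocol: 'n_cycles' must be >= 1")
  if (heat_hold < 0 || cool_hold < 0)
    stop("cycle_protocol: holds must be >= 0")
  if (tolerance_band <= 0)
    stop("cycle_protocol: 'tolerance_band' must be > 0")
  structure(list(setpoint = setpoint, n_cycles = n_cycles,
                 heat_hold = heat_hold, cool_hold = cool_hold,
                 tolerance_band = tolerance_band),
            class = "cycle_protocol")
}

#' Run a closed-loop thermal cycling protocol
#'
#' Simulates the PID-controlled block heater driving the two-node plant
#' through `n_cycles` of (heat to set point, hold, heater off, cool to the
#' ambient band, hold). The PID acts on the block thermocouple, as in the
#' hardware; the dish strip runs at constant power during heating phases and
#' is off while cooling. Phase transitions are gated on the dish channel
#' (the slowest node) entering the tolerance band.
#'
#' @param protocol A `cycle_protocol`.
#' @param pid A `pid_params`; `sample_interval` must be a multiple of its `dt`.
#' @param plant A `plant_params`.
#' @param sample_interval Logging interval (s).
#' @param seed Integer seed for the measurement noise stream.
#' @param noise_sd Gaussian measurement noise sd added to the logged
#'   temperatures (degree C); 0 disables noise.
#' @param max_phase_s Timeout per phase (s); exceeding it without entering
#'   the band raises a non-convergence error.
#' @return A [temperature_log()].
#' @export
run_protocol <- function(protocol, pid = pid_params(), plant = plant_params(),
                         sample_interval = 1, seed = 1L, noise_sd = 0,
                         max_phase_s = 3600) {
  stopifnot(inherits(protocol, "cycle_protocol"), inherits(pid, "pid_params"),
            inherits(plant, "plant_params"))
  if (sample_interval < pid$dt)
    stop("run_protocol: 'sample_interval' must be >= the PID control interval")
  steps_per_sample <- max(1L, round(sample_interval / pid$dt))

  st_plant <- plant_state(t_block = plant$t_amb, t_dish = plant$t_amb, time = 0)
  st_pid <- pid_state()
  band <- protocol$tolerance_band
  rng <- .seeded_rng(seed)

  time_s <- t_dish <- t_block <- duty_v <- sp_v <- numeric(0)
  push <- function(duty, sp) {
    nb <- if (noise_sd > 0) rng$norm(2, sd = noise_sd) else c(0, 0)
    time_s <<- c(time_s, st_plant$time)
    t_dish <<- c(t_dish, st_plant$t_dish + nb[1])
    t_block <<- c(t_block, st_plant$t_block + nb[2])
    duty_v <<- c(duty_v, duty)
    sp_v <<- c(sp_v, sp)
  }

  advance <- function(active_sp, dish_heater, stop_when, hold_s, phase_name) {
    # run until stop_when(state) is TRUE (then a further hold_s), logging as we go
    phase_start <- st_plant$time
    reached_at <- NA_real_
    repeat {
      for (k in seq_len(steps_per_sample)) {
        if (!is.null(active_sp)) {
          out <- pid_step(st_pid, pid, active_sp, st_plant$t_block)
          st_pid <<- out$state
          duty <- out$duty
        } else duty <- 0
        st_plant <<- step_plant(st_plant, plant, duty, pid$dt,
                                dish_heater = dish_heater)
      }
      push(duty, if (!is.null(active_sp)) active_sp else plant$t_amb)
      if (is.na(reached_at) && stop_when(st_plant)) reached_at <- st_plant$time
      if (!is.na(reached_at) && st_plant$time - reached_at >= hold_s) break
      if (is.na(reached_at) && st_plant$time - phase_start > max_phase_s)
        stop("run_protocol: ", phase_name,
             " phase did not enter the tolerance band within ", max_phase_s,
             " s; set point may be beyond the achievable equilibrium")
    }
  }

  push(0, protocol$setpoint)  # t = 0 at ambient, heater about to engage
  strip_on <- protocol$setpoint > plant$t_amb  # no dish strip when idling at ambient
  for (cyc in seq_len(protocol$n_cycles)) {
    st_pid <- pid_reset(st_pid)
    advance(protocol$setpoint, dish_heater = strip_on,
            stop_when = function(s) abs(s$t_dish - protocol$setpoint) <= band,
            hold_s = protocol$heat_hold, phase_name = "heating")
    advance(NULL, dish_heater = FALSE,
            stop_when = function(s) abs(s$t_dish - plant$t_amb) <= band,
            hold_s = protocol$cool_hold, phase_name = "cooling")
  }

  temperature_log(data.frame(time_s = time_s, t_dish_c = t_dish,
                             t_block_c = t_block, duty = duty_v,
                             setpoint_c = sp_v))
}

#' Run an extended heating trial at a fixed set point
#'
#' Heats from ambient and holds the set point for a fixed total duration
#' with no cooling cycling -- the protocol used for hour-long stability
#' characterisation. The PID drives the block; the dish strip stays on.
#'
#' @param setpoint Target temperature (degree C).
#' @param duration_s Total trial duration (s).
#' @inheritParams run_protocol
#' @return A [temperature_log()].
#' @export
run_hold <- function(setpoint = 37, duration_s = 3600, pid = pid_params(),
                     plant = plant_params(), sample_interval = 1,
                     seed = 1L, noise_sd = 0) {
  stopifnot(inherits(pid, "pid_params"), inherits(plant, "plant_params"))
  if (sample_interval < pid$dt)
    stop("run_hold: 'sample_interval' must be >= the PID control interval")
  steps_per_sample <- max(1L, round(sample_interval / pid$dt))
  st_plant <- plant_state(t_block = plant$t_amb, t_dish = plant$t_amb)
  st_pid <- pid_state()
  rng <- .seeded_rng(seed)
  n_samp <- floor(duration_s / sample_interval) + 1L
  time_s <- t_dish <- t_block <- duty_v <- numeric(n_samp)
  duty <- 0
  for (i in seq_len(n_samp)) {
    nb <- if (noise_sd > 0) rng$norm(2, sd = noise_sd) else c(0, 0)
    time_s[i] <- st_plant$time
    t_dish[i] <- st_plant$t_dish + nb[1]
    t_block[i] <- st_plant$t_block + nb[2]
    duty_v[i] <- duty
    if (i == n_samp) break
    for (k in seq_len(steps_per_sample)) {
      out <- pid_step(st_pid, pid, setpoint, st_plant$t_block)
      st_pid <- out$state
      duty <- out$duty
      st_plant <- step_plant(st_plant, plant, duty, pid$dt, dish_heater = TRUE)
    }
  }
  temperature_log(data.frame(time_s = time_s, t_dish_c = t_dish,
                             t_block_c = t_block, duty = duty_v,
                             setpoint_c = setpoint))
}

.log_channel <- function(log, channel = c("dish", "block")) {
  channel <- match.arg(channel)
  if (channel == "dish") log$t_dish_c else log$t_block_c
}

# Split a log into phases from steps in the setpoint column.
# Returns a data.frame: start index, end index, target, direction.
.log_phases <- function(log) {
  r <- rle(log$setpoint_c)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  n <- length(r$values)
  dir <- character(n)
  if (n == 1L) {
    dir <- "heating"
  } else {
    for (i in seq_len(n)) {
      if (i == 1L) {
        dir[i] <- if (r$values[1] >= max(r$values)) "heating" else "cooling"
      } else {
        dir[i] <- if (r$values[i] > r$values[i - 1L]) "heating" else "cooling"
      }
    }
  }
  data.frame(start = starts, end = ends, target = r$values, direction = dir,
             stringsAsFactors = FALSE)
}

#' Heating and cooling latency from a temperature log
#'
#' Latency is measured per phase as the time from phase start until the
#' chosen channel first enters the band `[target - band, target + band]`
#' and remains inside for at least `dwell` seconds. The heating target is
#' the active set point; the cooling target is ambient (the set-point column
#' value logged during cooling phases).
#'
#' @param log A [temperature_log()].
#' @param channel `"dish"` or `"block"`.
#' @param direction `"heating"` or `"cooling"`.
#' @param band Band half-width (degree C).
#' @param dwell Required continuous dwell inside the band (s).
#' @return A list of class `latency_result` with `per_cycle` latencies in
#'   seconds (`NA` where the band was never reached), `reached` flags,
#'   `mean` and `sd`.
#' @export
measure_latency <- function(log, channel = c("dish", "block"),
                            direction = c("heating", "cooling"),
                            band = 0.5, dwell = 0) {
  stopifnot(inherits(log, "temperature_log"))
  channel <- match.arg(channel)
  direction <- match.arg(direction)
  temp <- .log_channel(log, channel)
  phases <- .log_phases(log)
  phases <- phases[phases$direction == direction, , drop = FALSE]
  if (direction == "cooling" && nrow(phases) == 0)
    stop("measure_latency: log contains no cooling transitions")
  if (nrow(phases) == 0)
    stop("measure_latency: log contains no ", direction, " phases")

  lat <- rep(NA_real_, nrow(phases))
  for (i in seq_len(nrow(phases))) {
    idx <- phases$start[i]:phases$end[i]
    inside <- abs(temp[idx] - phases$target[i]) <= band
    t_phase <- log$time_s[idx]
    for (j in seq_along(idx)) {
      if (!inside[j]) next
      # continuous run from j covering >= dwell seconds
      k <- j
      while (k < length(idx) && inside[k + 1L] &&
             t_phase[k + 1L] - t_phase[j] <= dwell) k <- k + 1L
      if (t_phase[k] - t_phase[j] >= dwell) {
        lat[i] <- t_phase[j] - t_phase[1L]
        break
      }
    }
  }
  structure(list(per_cycle = lat, reached = !is.na(lat),
                 mean = mean(lat, na.rm = TRUE),
                 sd = stats::sd(lat, na.rm = TRUE),
                 channel = channel, direction = direction,
                 band = band, dwell = dwell),
            class = "latency_result")
}

#' Summary statistics of a temperature log window
#'
#' Computes mean, sample standard deviation (n - 1 denominator), minimum,
#' maximum, range and interquartile range (linear-interpolation quantiles)
#' of one channel over an analysis window. The `"after-first-reach"` window
#' starts at the channel's first entry into the tolerance band around the
#' maximum logged set point, matching how hold-phase stability is reported.
#'
#' @param log A [temperature_log()].
#' @param channel `"dish"` or `"block"`.
#' @param window `"after-first-reach"` or a numeric `c(start_s, end_s)`.
#' @param band Band half-width used by `"after-first-reach"` (degree C).
#' @return A list of class `log_stats` with fields `mean`, `sd`, `min`,
#'   `max`, `range`, `iqr`, `n` and `window`.
#' @export
log_stats <- function(log, channel = c("dish", "block"),
                      window = "after-first-reach", band = 0.5) {
  stopifnot(inherits(log, "temperature_log"))
  channel <- match.arg(channel)
  temp <- .log_channel(log, channel)

  if (identical(window, "after-first-reach")) {
    target <- max(log$setpoint_c)
    hit <- which(abs(temp - target) <= band)
    if (!length(hit))
      stop("log_stats: channel never entered the band around the set point")
    keep <- seq(hit[1L], nrow(log))
  } else if (is.numeric(window) && length(window) == 2L) {
    keep <- which(log$time_s >= window[1] & log$time_s <= window[2])
  } else stop("log_stats: 'window' must be \"after-first-reach\" or c(start, end)")
  if (!length(keep)) stop("log_stats: empty analysis window")

  x <- temp[keep]
  qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  structure(list(mean = mean(x),
                 sd = if (length(x) > 1) stats::sd(x) else 0,
                 min = min(x), max = max(x), range = max(x) - min(x),
                 iqr = qs[2] - qs[1], n = length(x),
                 window = c(log$time_s[keep[1L]], log$time_s[keep[length(keep)]])),
            class = "log_stats")
}

#' @export
print.log_stats <- function(x, ...) {
  cat(sprintf(
    "Temperature log statistics (n = %d, window %.0f-%.0f s)\n", x$n,
    x$window[1], x$window[2]))
  cat(sprintf("  mean %.2f degC  sd %.2f  min %.2f  max %.2f  range %.2f  IQR %.2f\n",
              x$mean, x$sd, x$min, x$max, x$range, x$iqr))
  invisible(x)
}

#' @export
print.latency_result <- function(x, ...) {
  cat(sprintf("%s %s latency: mean %.1f s (%.2f min), sd %.1f s over %d cycle(s)\n",
              x$channel, x$direction, x$mean, x$mean / 60,
              x$sd, length(x$per_cycle)))
  invisible(x)
}
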