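#' Published 37 degree C latency targets
#'
#' The four heating/cooling latencies reported for the dish and waterblock
#' channels at a 37 degree C set point, in minutes: dish 5.50 (heating) and
#' 5.44 (cooling); block 1.68 (heating) and 5.85 (cooling).
#'
#' @return A data frame with columns `channel`, `direction`, `setpoint`,
#'   `minutes`.
#' @export
latency_targets_37c <- function() {
  data.frame(
    channel   = c("dish", "dish", "block", "block"),
    direction = c("heating", "cooling", "heating", "cooling"),
    setpoint  = 37,
    minutes   = c(5.50, 5.44, 1.68, 5.85),
    stringsAsFactors = FALSE
  )
}

# Simulate one protocol and return the mean latency (s) for each target row.
.simulated_latencies <- function(targets, pid, plant, n_cycles = 1,
                                 band = 0.5, dwell = 0) {
  sp <- unique(targets$setpoint)
  out <- rep(NA_real_, nrow(targets))
  for (s in sp) {
    proto <- cycle_protocol(setpoint = s, n_cycles = n_cycles,
                            heat_hold = 120, cool_hold = 30,
                            tolerance_band = band)
    log <- tryCatch(
      run_protocol(proto, pid = pid, plant = plant, sample_interval = pid$dt,
                   noise_sd = 0, max_phase_s = 2400),
      error = function(e) NULL)
    rows <- which(targets$setpoint == s)
    for (i in rows) {
      if (is.null(log)) next
      res <- tryCatch(
        measure_latency(log, channel = targets$channel[i],
                        direction = targets$direction[i],
                        band = band, dwell = dwell),
        error = function(e) NULL)
      if (!is.null(res) && is.finite(res$mean)) out[i] <- res$mean
    }
  }
  out
}

#' Calibrate plant parameters against latency targets
#'
#' Fits selected plant parameters so that a closed-loop simulation under the
#' given PID reproduces a set of heating/cooling latency targets. The loss is
#' the sum of squared relative latency errors; the search is a bounded
#' derivative-free Nelder-Mead run in a logit-transformed box, so it is
#' deterministic given the starting plant and bounds. Targets a simulated
#' phase never reaches contribute a large penalty.
#'
#' @param targets Data frame with columns `channel` (`"dish"`/`"block"`),
#'   `direction` (`"heating"`/`"cooling"`), `setpoint` (degree C) and
#'   `minutes` (target latency). See [latency_targets_37c()].
#' @param pid A `pid_params` used in the closed loop.
#' @param bounds Named list of `c(lower, upper)` boxes for the free
#'   parameters (any of `c_block`, `c_dish`, `k_block_amb`, `k_dish_amb`,
#'   `k_tube`, `p_block_max`, `p_dish`).
#' @param start A `plant_params` supplying the starting point and all fixed
#'   parameters.
#' @param band,dwell Latency criterion (degree C half-band; dwell s).
#' @param maxit Maximum Nelder-Mead iterations.
#' @param residual_warn Relative-error threshold above which a
#'   calibration-failure warning is raised (per target).
#' @return The fitted `plant_params`, with attributes `residuals` (relative
#'   error per target) and `value` (final loss).
#' @export
calibrate_plant <- function(targets, pid = pid_params(),
                            bounds = list(
                              c_block = c(100, 600), c_dish = c(4, 80),
                              k_block_amb = c(0.5, 6), k_dish_amb = c(0.005, 0.6),
                              k_tube = c(0.5, 1), p_dish = c(0, 5)),
                            start = plant_params(), band = 0.5, dwell = 0,
                            maxit = 200, residual_warn = 0.1) {
  if (is.null(targets) || nrow(targets) == 0)
    stop("calibrate_plant: empty target set")
  needed <- c("channel", "direction", "setpoint", "minutes")
  if (!all(needed %in% names(targets)))
    stop("calibrate_plant: targets need columns ",
         paste(needed, collapse = ", "))
  free <- names(bounds)
  bad <- setdiff(free, c("c_block", "c_dish", "k_block_amb", "k_dish_amb",
                         "k_tube", "p_block_max", "p_dish"))
  if (length(bad))
    stop("calibrate_plant: unknown free parameters: ", paste(bad, collapse = ", "))

  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  to_z <- function(x) stats::qlogis(.clamp((x - lo) / (hi - lo), 1e-6, 1 - 1e-6))
  to_x <- function(z) lo + (hi - lo) * stats::plogis(z)

  make_plant <- function(x) {
    p <- unclass(start)
    p[free] <- as.list(x)
    do.call(plant_params, p[setdiff(names(p), character(0))])
  }
  target_s <- targets$minutes * 60
  obj <- function(z) {
    plant <- make_plant(to_x(z))
    sim <- .simulated_latencies(targets, pid, plant, band = band, dwell = dwell)
    rel <- (sim - target_s) / target_s
    rel[!is.finite(rel)] <- 10
    sum(rel^2)
  }

  z0 <- to_z(unlist(unclass(start)[free]))
  fit <- stats::optim(z0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-6))
  plant <- make_plant(to_x(fit$par))
  sim <- .simulated_latencies(targets, pid, plant, band = band, dwell = dwell)
  resid <- (sim - target_s) / target_s
  if (any(!is.finite(resid)) || max(abs(resid)) > residual_warn)
    warning("calibrate_plant: residual above ", residual_warn,
            "; returning best-found parameters")
  attr(plant, "residuals") <- resid
  attr(plant, "value") <- fit$value
  plant
}
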