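#' PID controller parameters
#'
#' Gains and bounds for the discrete-time proportional-integral-derivative
#' control law that drives the waterblock heater. Duty is normalised to
#' `[u_min, u_max]` (default `[0, 1]`); use [duty_to_pwm8()] for the 8-bit
#' firmware view.
#'
#' @param kp Proportional gain (duty per degree C). Must be >= 0.
#' @param ki Integral gain (duty per degree C second). Must be >= 0.
#' @param kd Derivative gain (duty seconds per degree C). Must be >= 0.
#'   The derivative acts on the raw error, `(e_t - e_{t-1}) / dt`, and is
#'   forced to zero on the first step after a reset.
#' @param dt Control interval in seconds (> 0).
#' @param u_min,u_max Output clamp bounds (dimensionless duty).
#' @param integral_limit Bound on the accumulated integral term, in
#'   degree C seconds (anti-windup by clamping). Default `1 / ki` so the
#'   integral contribution alone saturates at duty 1.
#' @return An object of class `pid_params`.
#' @examples
#' p <- pid_params(kp = 2, ki = 0.1, dt = 1)
#' @export
pid_params <- function(kp = 20, ki = 0.05, kd = 0, dt = 1,
                       u_min = 0, u_max = 1,
                       integral_limit = if (ki > 0) 1 / ki else Inf) {
  stopifnot(is.numeric(kp), is.numeric(ki), is.numeric(kd), is.numeric(dt))
  if (!is.finite(dt) || dt <= 0)
    stop("pid_params: 'dt' must be a positive, finite control interval (s)")
  if (kp < 0 || ki < 0 || kd < 0)
    stop("pid_params: gains must be non-negative")
  if (!(u_min < u_max))
    stop("pid_params: 'u_min' must be strictly less than 'u_max'")
  if (integral_limit < 0)
    stop("pid_params: 'integral_limit' must be non-negative")
  structure(
    list(kp = kp, ki = ki, kd = kd, dt = dt,
         u_min = u_min, u_max = u_max, integral_limit = integral_limit),
    class = "pid_params"
  )
}

#' Fresh PID controller state
#'
#' @return An object of class `pid_state` with a zero integral accumulator,
#'   no previous error and the first-step flag unset.
#' @seealso [pid_step()], [pid_reset()]
#' @export
pid_state <- function() {
  structure(
    list(integral_accum = 0, prev_error = NA_real_, initialized = FALSE),
    class = "pid_state"
  )
}

#' Reset a PID controller state
#'
#' Zeroes the integral accumulator and clears the error history, so the next
#' [pid_step()] behaves exactly like the first step of a fresh run.
#'
#' @param state A `pid_state`.
#' @return A zeroed `pid_state`.
#' @export
pid_reset <- function(state) {
  stopifnot(inherits(state, "pid_state"))
  pid_state()
}

#' One step of the discrete PID control law
#'
#' Computes the error `setpoint - measurement`, accumulates it into the
#' integral term (clamped to `+/- integral_limit`), forms the derivative as
#' the backward difference of the error (zero on the first step), and returns
#' the clamped duty command.
#'
#' @param state A `pid_state`.
#' @param params A `pid_params`.
#' @param setpoint Target temperature (degree C), finite.
#' @param measurement Measured temperature (degree C), finite.
#' @return A list with elements `duty` (clamped command) and `state`
#'   (the updated `pid_state`).
#' @examples
#' st <- pid_state()
#' pid_step(st, pid_params(kp = 1, ki = 0, u_min = -1, u_max = 1), 37.5, 37)$duty
#' @export
pid_step <- function(state, params, setpoint, measurement) {
  stopifnot(inherits(state, "pid_state"), inherits(params, "pid_params"))
  if (!is.finite(setpoint) || !is.finite(measurement))
    stop("pid_step: 'setpoint' and 'measurement' must be finite")
  error <- setpoint - measurement

  accum <- state$integral_accum + error * params$dt
  accum <- max(-params$integral_limit, min(params$integral_limit, accum))

  p_term <- params$kp * error
  i_term <- params$ki * accum
  d_term <- if (state$initialized)
    params$kd * (error - state$prev_error) / params$dt else 0

  duty <- max(params$u_min, min(params$u_max, p_term + i_term + d_term))
  new_state <- structure(
    list(integral_accum = accum, prev_error = error, initialized = TRUE),
    class = "pid_state"
  )
  list(duty = duty, state = new_state)
}

#' Convert between normalised duty and 8-bit PWM counts
#'
#' Firmware-facing view of the duty command: `0..255` PWM as written to an
#' 8-bit timer register.
#'
#' @param duty Normalised duty in `[0, 1]`.
#' @param pwm Integer PWM count in `0..255`.
#' @return `duty_to_pwm8()` returns an integer count; `pwm8_to_duty()` a
#'   duty in `[0, 1]`.
#' @export
duty_to_pwm8 <- function(duty) {
  if (any(duty < 0 | duty > 1)) stop("duty must lie in [0, 1]")
  as.integer(round(duty * 255))
}

#' @rdname duty_to_pwm8
#' @export
pwm8_to_duty <- function(pwm) {
  if (any(pwm < 0 | pwm > 255)) stop("pwm must lie in 0..255")
  pwm / 255
}
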