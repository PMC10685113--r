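#' Lumped-parameter thermal plant
#'
#' Two-node model of the heat path: a PID-heated aluminium waterblock warms
#' recirculating solution which is carried (with some loss along the tubing)
#' to the imaging dish; the dish additionally carries a constant-power
#' perimeter heating strip and both nodes lose heat to ambient.
#'
#' Energy balance per node (explicit form integrated by [step_plant()]):
#' \deqn{C_b \dot T_b = u P_{max} - k_{ba}(T_b - T_a) - q (T_b - T_d)}
#' \deqn{C_d \dot T_d = P_d + q (T_{in} - T_d) - k_{da}(T_d - T_a)}
#' with advective conductance \eqn{q} = `flow_rate * fluid_heat_capacity / 60`
#' (W per degree C) and dish inlet temperature
#' \eqn{T_{in} = T_a + k_{tube}(T_b - T_a)}: the tube retains a fraction
#' `k_tube` of the block's excess temperature.
#'
#' The shipped defaults were calibrated so that a closed-loop 37 degree C
#' protocol under the default PID gains reproduces the four published heating
#' and cooling latencies (dish 5.50 / 5.44 min, block 1.68 / 5.85 min); see
#' [calibrate_plant()].
#'
#' @param c_block Block thermal capacity (J per degree C).
#' @param c_dish Dish plus medium thermal capacity (J per degree C).
#' @param k_block_amb,k_dish_amb Loss coefficients to ambient (W per degree C).
#' @param k_tube Fractional heat retention of the fluid between block outlet
#'   and dish inlet, in `[0, 1]`.
#' @param p_block_max Block heater power at duty 1 (W).
#' @param p_dish Constant dish-strip power while heating (W).
#' @param flow_rate Volumetric flow (mL/min).
#' @param fluid_heat_capacity Volumetric heat capacity of the solution
#'   (J per mL per degree C); 4.18 for aqueous saline.
#' @param t_amb Ambient temperature (degree C).
#' @param gradient_offset Reported centre-to-periphery dish gradient
#'   (degree C); carried for reporting, not used in the dynamics.
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(c_block = 224.23, c_dish = 11.272,
                         k_block_amb = 2.3776, k_dish_amb = 0.0865,
                         k_tube = 0.8364, p_block_max = 60, p_dish = 1.7587,
                         flow_rate = 2, fluid_heat_capacity = 4.18,
                         t_amb = 20, gradient_offset = 2) {
  vals <- c(c_block = c_block, c_dish = c_dish, k_block_amb = k_block_amb,
            k_dish_amb = k_dish_amb, p_block_max = p_block_max,
            p_dish = p_dish, flow_rate = flow_rate,
            fluid_heat_capacity = fluid_heat_capacity)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("plant_params: capacities, powers, coefficients and flow must be finite and >= 0")
  if (c_block <= 0 || c_dish <= 0)
    stop("plant_params: thermal capacities must be strictly positive")
  if (k_tube < 0 || k_tube > 1)
    stop("plant_params: 'k_tube' must lie in [0, 1]")
  structure(
    list(c_block = c_block, c_dish = c_dish,
         k_block_amb = k_block_amb, k_dish_amb = k_dish_amb,
         k_tube = k_tube, p_block_max = p_block_max, p_dish = p_dish,
         flow_rate = flow_rate, fluid_heat_capacity = fluid_heat_capacity,
         t_amb = t_amb, gradient_offset = gradient_offset),
    class = "plant_params"
  )
}

#' Thermal plant state
#'
#' @param t_block Block temperature (degree C).
#' @param t_dish Dish temperature (degree C).
#' @param time Elapsed time (s).
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(t_block = 20, t_dish = 20, time = 0) {
  if (!is.finite(t_block) || !is.finite(t_dish))
    stop("plant_state: temperatures must be finite")
  structure(list(t_block = t_block, t_dish = t_dish, time = time),
            class = "plant_state")
}

# Advective conductance, W/degC
.q_flow <- function(params) params$flow_rate * params$fluid_heat_capacity / 60

#' Advance the plant by one control interval
#'
#' Explicit (forward Euler) integration of the two-node energy balance.
#' The integration error is O(dt); to keep the explicit scheme stable and
#' accurate the interval is internally sub-divided so that no sub-step
#' exceeds one fifth of the smallest nodal time constant
#' `C / (k_amb + q)`.
#'
#' @param state A `plant_state`.
#' @param params A `plant_params`.
#' @param duty Heater command in `[0, 1]` applied to the block.
#' @param dt Interval to integrate over (s, > 0).
#' @param dish_heater Logical; whether the constant-power dish strip is on.
#' @return The advanced `plant_state`.
#' @export
step_plant <- function(state, params, duty, dt, dish_heater = TRUE) {
  stopifnot(inherits(state, "plant_state"), inherits(params, "plant_params"))
  if (!is.finite(duty) || duty < 0 || duty > 1)
    stop("step_plant: 'duty' must lie in [0, 1]")
  if (!is.finite(dt) || dt <= 0)
    stop("step_plant: 'dt' must be positive")

  q <- .q_flow(params)
  tau_b <- params$c_block / max(params$k_block_amb + q, 1e-12)
  tau_d <- params$c_dish / max(params$k_dish_amb + q, 1e-12)
  n_sub <- max(1L, ceiling(dt / (0.2 * min(tau_b, tau_d))))
  h <- dt / n_sub

  tb <- state$t_block
  td <- state$t_dish
  ta <- params$t_amb
  p_d <- if (dish_heater) params$p_dish else 0
  for (i in seq_len(n_sub)) {
    t_in <- ta + params$k_tube * (tb - ta)
    dtb <- (duty * params$p_block_max -
              params$k_block_amb * (tb - ta) -
              q * (tb - td)) / params$c_block
    dtd <- (p_d + q * (t_in - td) -
              params$k_dish_amb * (td - ta)) / params$c_dish
    tb <- tb + h * dtb
    td <- td + h * dtd
  }
  plant_state(t_block = tb, t_dish = td, time = state$time + dt)
}
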