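#' Gravity-feed flow parameters
#'
#' Physical quantities for sizing a gravity-fed perfusion line as an
#' alternative to a peristaltic pump.
#'
#' @param rho Liquid density (kg/m^3).
#' @param g Gravitational acceleration (m/s^2).
#' @param h Liquid height above the outlet (m).
#' @param delta_p Pressure difference across the tubing (Pa).
#' @param r Tubing internal radius (m).
#' @param eta Dynamic viscosity (Pa s).
#' @param length Tubing length (m).
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(rho = 1000, g = 9.81, h = 0, delta_p = 0,
                        r = 5e-4, eta = 1e-3, length = 1) {
  vals <- c(rho = rho, g = g, h = h, delta_p = delta_p, r = r,
            eta = eta, length = length)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("flow_params: all physical quantities must be finite and >= 0")
  structure(as.list(vals), class = "flow_params")
}

#' Hydrostatic pressure of a liquid column
#'
#' `p = rho * g * h`, the driving pressure available from a reservoir raised
#' a height `h` above the dish.
#'
#' @param flow A `flow_params`.
#' @return Pressure in Pa.
#' @examples
#' hydrostatic_pressure(flow_params(rho = 1000, g = 9.81, h = 0.1)) # 981 Pa
#' @export
hydrostatic_pressure <- function(flow) {
  stopifnot(inherits(flow, "flow_params"))
  flow$rho * flow$g * flow$h
}

#' Laminar flow through tubing (Hagen-Poiseuille)
#'
#' `Q = pi * delta_p * r^4 / (8 * eta * L)`.
#'
#' @param flow A `flow_params` with `eta > 0` and `length > 0`.
#' @return Volumetric flow in m^3/s, with attribute `ml_per_min` giving the
#'   laboratory-units view.
#' @examples
#' q <- poiseuille_flow(flow_params(delta_p = 981, r = 5e-4, eta = 1e-3, length = 1))
#' attr(q, "ml_per_min")
#' @export
poiseuille_flow <- function(flow) {
  stopifnot(inherits(flow, "flow_params"))
  if (flow$eta <= 0 || flow$length <= 0)
    stop("poiseuille_flow: 'eta' and 'length' must be strictly positive")
  q <- pi * flow$delta_p * flow$r^4 / (8 * flow$eta * flow$length)
  structure(q, ml_per_min = q * 1e6 * 60)
}
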