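#' Ideal-gas thermodynamic state
#'
#' Bundles the quantities needed by ideal shock-tube theory: heat-capacity
#' ratio, static pressure, temperature and the specific gas constant. The
#' sound speed \eqn{a = \sqrt{\gamma R T}} is derived on construction.
#'
#' Defaults describe the driven section of an air-filled tube at standard
#' atmospheric pressure (101.3 kPa) and 293 K.
#'
#' @param gamma Heat-capacity ratio (dimensionless), must exceed 1.
#' @param pressure Static pressure in Pa.
#' @param temperature Temperature in K.
#' @param gas_constant Specific gas constant in J/(kg K).
#' @return An object of class `gas_state`: a list with fields `gamma`,
#'   `pressure`, `temperature`, `gas_constant`, `sound_speed` (m/s) and
#'   `density` (kg/m^3).
#' @examples
#' air <- gas_state()
#' air$sound_speed
#' @export
gas_state <- function(gamma = 1.4, pressure = 101.3e3, temperature = 293,
                      gas_constant = 287) {
  stopifnot(gamma > 1, pressure > 0, temperature > 0, gas_constant > 0)
  out <- list(
    gamma = gamma, pressure = pressure, temperature = temperature,
    gas_constant = gas_constant,
    sound_speed = sqrt(gamma * gas_constant * temperature),
    density = pressure / (gas_constant * temperature)
  )
  structure(out, class = "gas_state")
}

#' @export
print.gas_state <- function(x, ...) {
  cat(sprintf(
    "<gas_state> gamma = %.3f, p = %.4g Pa, T = %.1f K, a = %.2f m/s\n",
    x$gamma, x$pressure, x$temperature, x$sound_speed
  ))
  invisible(x)
}

#' Shock-tube initial condition
#'
#' Pairs a driver (state 4) and driven (state 1) gas and records the diaphragm
#' pressure ratio P4/P1.
#'
#' @param driver,driven [gas_state()] objects for the high-pressure chamber
#'   and low-pressure channel.
#' @return An object of class `shock_tube_condition` with fields `driver`,
#'   `driven` and `diaphragm_ratio`.
#' @export
shock_tube_condition <- function(driver, driven = gas_state()) {
  stopifnot(inherits(driver, "gas_state"), inherits(driven, "gas_state"))
  ratio <- driver$pressure / driven$pressure
  if (ratio < 1) {
    stop("driver pressure must be at least the driven pressure (P4/P1 >= 1)")
  }
  structure(
    list(driver = driver, driven = driven, diaphragm_ratio = ratio),
    class = "shock_tube_condition"
  )
}

#' Air-filled shock tube at a given diaphragm pressure ratio
#'
#' Convenience constructor: both sections are air (`gamma` 1.4, 287 J/(kg K))
#' at a common temperature, so the driver and driven sound speeds are equal,
#' the idealisation used when the operating point of the tube is quoted as a
#' bare P4/P1 number.
#'
#' @param p4_over_p1 Diaphragm pressure ratio (>= 1).
#' @param p1 Driven-section pressure in Pa.
#' @param temperature Common temperature in K.
#' @param gamma Heat-capacity ratio for both sections.
#' @return A `shock_tube_condition`.
#' @export
air_shock_tube <- function(p4_over_p1, p1 = 101.3e3, temperature = 293,
                           gamma = 1.4) {
  stopifnot(p4_over_p1 >= 1)
  driven <- gas_state(gamma = gamma, pressure = p1, temperature = temperature)
  driver <- gas_state(gamma = gamma, pressure = p1 * p4_over_p1,
                      temperature = temperature)
  shock_tube_condition(driver, driven)
}

#' Normal-shock jump relations
#'
#' Rankine-Hugoniot relations for a normal shock of Mach number `Ms` running
#' into a quiescent gas. Returns the post/pre static pressure, density and
#' temperature ratios and the post-shock gas speed in the laboratory frame,
#' \eqn{u_2 = \frac{2 a_1}{\gamma + 1}\left(M_s - 1/M_s\right)}.
#'
#' @param Ms Incident shock Mach number, >= 1.
#' @param gas The undisturbed (driven) gas, a [gas_state()]. Supplies
#'   \eqn{\gamma} and the sound speed used for `u2`.
#' @return A one-row tibble with columns `Ms`, `p_ratio`, `rho_ratio`,
#'   `T_ratio`, `u2` (m/s).
#' @examples
#' shock_from_mach(2)            # p2/p1 = 4.5 for air
#' @export
shock_from_mach <- function(Ms, gas = gas_state()) {
  if (any(Ms < 1)) stop("Ms must be >= 1: no shock exists below the sonic limit")
  g <- gas$gamma
  p_ratio <- (2 * g * Ms^2 - (g - 1)) / (g + 1)
  rho_ratio <- ((g + 1) * Ms^2) / ((g - 1) * Ms^2 + 2)
  tibble::tibble(
    Ms = Ms,
    p_ratio = p_ratio,
    rho_ratio = rho_ratio,
    T_ratio = p_ratio / rho_ratio,
    u2 = 2 * gas$sound_speed / (g + 1) * (Ms - 1 / Ms)
  )
}

#' Diaphragm pressure ratio required for a given shock Mach number
#'
#' The ideal shock-tube closure: for an instantaneously and completely
#' removed diaphragm (no wall friction or heat exchange),
#' \deqn{\frac{P_4}{P_1} = \frac{2\gamma_1 M_s^2 - (\gamma_1 - 1)}{\gamma_1 + 1}
#'   \left[1 - \frac{\gamma_4 - 1}{\gamma_1 + 1}\frac{a_1}{a_4}
#'   \left(M_s - \frac{1}{M_s}\right)\right]^{-2\gamma_4/(\gamma_4 - 1)}.}
#'
#' @param Ms Incident shock Mach number, >= 1.
#' @param condition A [shock_tube_condition()]; defaults to an air/air tube
#'   with equal sound speeds (the pressure ratio then depends on `Ms` only).
#' @return The diaphragm pressure ratio P4/P1 (dimensionless).
#' @examples
#' p4p1_from_mach(1.859)   # about 22, the 22.5 operating point of a real tube
#' @export
p4p1_from_mach <- function(Ms, condition = air_shock_tube(22.5)) {
  if (any(Ms < 1)) stop("Ms must be >= 1")
  g1 <- condition$driven$gamma
  g4 <- condition$driver$gamma
  a1 <- condition$driven$sound_speed
  a4 <- condition$driver$sound_speed
  p21 <- (2 * g1 * Ms^2 - (g1 - 1)) / (g1 + 1)
  bracket <- 1 - (g4 - 1) / (g1 + 1) * (a1 / a4) * (Ms - 1 / Ms)
  if (any(bracket <= 0)) {
    stop("infeasible Mach number: the driver cannot sustain this shock ",
         "(expansion bracket <= 0)")
  }
  p21 * bracket^(-2 * g4 / (g4 - 1))
}

#' Shock Mach number produced by a given diaphragm pressure ratio
#'
#' Inverts [p4p1_from_mach()] by bracketed bisection followed by a Newton
#' polish; the forward relation is strictly increasing in `Ms` on its
#' feasible domain, so the root is unique.
#'
#' @param ratio Diaphragm pressure ratio P4/P1, >= 1.
#' @param condition A [shock_tube_condition()]; defaults to an air/air tube.
#' @param tol Relative tolerance on `Ms`.
#' @return The incident shock Mach number.
#' @examples
#' mach_from_p4p1(22.5)    # about 1.866
#' @export
mach_from_p4p1 <- function(ratio, condition = air_shock_tube(22.5),
                           tol = 1e-12) {
  if (ratio < 1) stop("P4/P1 must be >= 1")
  if (ratio == 1) return(1)
  f <- function(Ms) p4p1_from_mach(Ms, condition) - ratio

  # expansion bracket vanishes at Ms_max; stay strictly inside
  g1 <- condition$driven$gamma
  g4 <- condition$driver$gamma
  a14 <- condition$driven$sound_speed / condition$driver$sound_speed
  k <- (g4 - 1) / (g1 + 1) * a14
  ms_max <- (1 + sqrt(1 + 4 * k^2)) / (2 * k)  # root of 1 - k (Ms - 1/Ms) = 0
  hi <- min(10, ms_max * (1 - 1e-9))
  lo <- 1
  if (f(hi) < 0) {
    stop("infeasible diaphragm ratio: exceeds what this driver can produce ",
         "within the feasible Mach range")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < tol * mid) break
  }
  ms <- (lo + hi) / 2
  # Newton polish with numerical derivative
  for (i in 1:5) {
    h <- 1e-7 * ms
    d <- (f(ms + h) - f(ms - h)) / (2 * h)
    step <- f(ms) / d
    ms_new <- ms - step
    if (ms_new > lo && ms_new < hi) ms <- ms_new
    if (abs(step) < tol * ms) break
  }
  ms
}

#' Shock Mach number from transducer arrival times
#'
#' Estimates the incident shock speed as the least-squares slope of position
#' against arrival time over a line of pressure transducers, and divides by
#' the driven-gas sound speed to obtain the shock Mach number.
#'
#' @param positions Transducer positions in m, strictly increasing.
#' @param times Arrival times in s, strictly increasing.
#' @param gas Driven [gas_state()], supplies the sound speed.
#' @return A list with `Ms`, `speed` (m/s, the fitted slope) and
#'   `interval_speeds` (m/s, finite-difference speeds between neighbours).
#' @examples
#' mach_from_arrivals(c(0, 1, 2), c(0, 1e-3, 2e-3))
#' @export
mach_from_arrivals <- function(positions, times, gas = gas_state()) {
  if (length(positions) < 2 || length(positions) != length(times)) {
    stop("need at least two (position, time) pairs")
  }
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(diff(times) <= 0)) {
    stop("arrival times must be strictly increasing: transducers mis-ordered ",
         "or arrivals mis-detected")
  }
  speed <- stats::cov(positions, times) / stats::var(times)
  list(
    Ms = speed / gas$sound_speed,
    speed = speed,
    interval_speeds = diff(positions) / diff(times)
  )
}
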