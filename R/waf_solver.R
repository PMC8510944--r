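#' Axisymmetric (or planar) 2D grid with solid masking
#'
#' A uniform finite-volume grid in axial (`z`) and radial (`r`) coordinates.
#' Cells flagged in `mask` are solid: they carry no state and present
#' reflective walls to their fluid neighbours (stair-stepped geometry).
#'
#' @param nz,nr Number of cells in z and r.
#' @param dz,dr Cell sizes in m.
#' @param mask Integer or logical `nz x nr` matrix, `TRUE`/`1` = solid.
#'   Defaults to all-fluid.
#' @param axisym If `TRUE` the radial direction carries cylindrical geometry
#'   (r-weighted flux volumes and the `p/r` source); if `FALSE` the grid is
#'   planar 2D Cartesian.
#' @param bc Length-4 character vector of domain-edge conditions in order
#'   (z-min, z-max, r-min, r-max); each `"reflective"` or `"transmissive"`.
#' @return An object of class `axi_grid`.
#' @export
axi_grid <- function(nz, nr, dz, dr = dz, mask = NULL, axisym = TRUE,
                     bc = c("reflective", "reflective", "reflective",
                            "reflective")) {
  stopifnot(nz >= 1, nr >= 1, dz > 0, dr > 0, length(bc) == 4)
  if (is.null(mask)) mask <- matrix(0L, nz, nr)
  mask <- matrix(as.integer(mask != 0), nz, nr)
  bc_code <- match(match.arg(bc, c("reflective", "transmissive"),
                             several.ok = TRUE),
                   c("reflective", "transmissive")) - 1L
  if (length(bc_code) != 4) stop("bc must name 4 edge conditions")
  structure(list(
    nz = as.integer(nz), nr = as.integer(nr), dz = dz, dr = dr,
    mask = mask, axisym = axisym, bc = as.integer(bc_code),
    z_centers = (seq_len(nz) - 0.5) * dz,
    r_centers = (seq_len(nr) - 0.5) * dr
  ), class = "axi_grid")
}

#' @export
print.axi_grid <- function(x, ...) {
  cat(sprintf(
    "<axi_grid> %d x %d cells (%.3g x %.3g m), %s, %d solid cells\n",
    x$nz, x$nr, x$nz * x$dz, x$nr * x$dr,
    if (x$axisym) "axisymmetric" else "planar", sum(x$mask)
  ))
  invisible(x)
}

#' Conserved-variable field on an [axi_grid()]
#'
#' Holds density, momenta and total energy density per cell, plus the
#' simulation time. Construct from primitive fields with [axi_field()].
#'
#' @param grid An [axi_grid()].
#' @param density Matrix `nz x nr`, kg/m^3, or a scalar.
#' @param pressure Matrix or scalar, Pa.
#' @param u_z,u_r Velocity components, m/s (matrix or scalar).
#' @param gamma Heat-capacity ratio.
#' @param time Simulation time, s.
#' @return An object of class `axi_field` with matrices `density`, `mom_z`,
#'   `mom_r`, `energy`.
#' @export
axi_field <- function(grid, density, pressure, u_z = 0, u_r = 0,
                      gamma = 1.4, time = 0) {
  stopifnot(inherits(grid, "axi_grid"))
  full <- function(x) {
    if (length(x) == 1) matrix(x, grid$nz, grid$nr) else {
      stopifnot(all(dim(x) == c(grid$nz, grid$nr))); x
    }
  }
  rho <- full(density); p <- full(pressure)
  uz <- full(u_z); ur <- full(u_r)
  fluid <- grid$mask == 0
  if (any(rho[fluid] <= 0) || any(p[fluid] <= 0)) {
    stop("density and pressure must be positive in all fluid cells")
  }
  en <- p / (gamma - 1) + 0.5 * rho * (uz^2 + ur^2)
  # solid cells carry placeholder ambient-like state; sweeps never read them
  structure(list(
    density = rho, mom_z = rho * uz, mom_r = rho * ur, energy = en,
    gamma = gamma, time = time
  ), class = "axi_field")
}

#' Primitive fields of an `axi_field`
#'
#' @param field An [axi_field()].
#' @param grid The matching [axi_grid()]; solid cells come back as `NA`.
#' @return List of matrices `density`, `u_z`, `u_r`, `pressure`.
#' @export
primitives <- function(field, grid) {
  rho <- field$density
  uz <- field$mom_z / rho
  ur <- field$mom_r / rho
  p <- (field$gamma - 1) *
    (field$energy - 0.5 * (field$mom_z^2 + field$mom_r^2) / rho)
  solid <- grid$mask != 0
  rho[solid] <- NA; uz[solid] <- NA; ur[solid] <- NA; p[solid] <- NA
  list(density = rho, u_z = uz, u_r = ur, pressure = p)
}

#' Total mass and energy of a field (physical, geometry-weighted)
#'
#' For an axisymmetric grid each cell is weighted by its annular volume
#' \eqn{2\pi r_c \Delta r \Delta z}; planar grids use \eqn{\Delta z \Delta r}.
#' Used for conservation checks on closed domains.
#'
#' @inheritParams primitives
#' @return Named numeric vector `c(mass = , energy = )`.
#' @export
field_totals <- function(field, grid) {
  w <- if (grid$axisym) {
    matrix(2 * pi * grid$r_centers * grid$dr * grid$dz,
           grid$nz, grid$nr, byrow = TRUE)
  } else {
    matrix(grid$dz * grid$dr, grid$nz, grid$nr)
  }
  w[grid$mask != 0] <- 0
  c(mass = sum(field$density * w), energy = sum(field$energy * w))
}

#' Advance a field by one split WAF step
#'
#' One dimensionally split update (z- and r-sweeps) of the compressible
#' Euler equations with the TVD WAF flux. The time step must satisfy the
#' CFL condition; [cfl_time_step()] provides a safe value.
#'
#' @param field An [axi_field()].
#' @param grid The matching [axi_grid()].
#' @param dt Time step in s.
#' @param r_first Sweep order; alternating orders across steps restores
#'   formal second-order splitting accuracy.
#' @return The updated `axi_field` at `time + dt`.
#' @export
advance <- function(field, grid, dt, r_first = FALSE) {
  out <- advance_cpp(field$density, field$mom_z, field$mom_r, field$energy,
                     grid$mask, grid$dz, grid$dr, field$gamma, dt,
                     grid$axisym, r_first, grid$bc, field$time)
  structure(list(
    density = out$density, mom_z = out$mom_z, mom_r = out$mom_r,
    energy = out$energy, gamma = field$gamma, time = field$time + dt
  ), class = "axi_field")
}

#' CFL-limited time step for a field
#'
#' @inheritParams advance
#' @param cfl Courant number, in (0, 1); 0.4 is the package default.
#' @return Time step in s.
#' @export
cfl_time_step <- function(field, grid, cfl = 0.4) {
  stopifnot(cfl > 0, cfl < 1)
  p <- (field$gamma - 1) *
    (field$energy - 0.5 * (field$mom_z^2 + field$mom_r^2) / field$density)
  a <- sqrt(field$gamma * p / field$density)
  sz <- (abs(field$mom_z / field$density) + a) / grid$dz
  sr <- (abs(field$mom_r / field$density) + a) / grid$dr
  s <- pmax(sz, sr)
  s[grid$mask != 0] <- 0
  cfl / max(s)
}

#' Run the axisymmetric solver with probes, monitors and snapshots
#'
#' Integrates an [axi_field()] to `t_end` with CFL-adaptive steps,
#' alternating sweep order. Probe pressures are recorded on a uniform output
#' grid; arrival monitors report the first time the maximum overpressure
#' over a cell group crosses `threshold`; pressure snapshots are taken at
#' requested times. The run is fully deterministic.
#'
#' @inheritParams advance
#' @param t_end End time, s.
#' @param cfl Courant number.
#' @param probes Optional 2-column matrix of 1-based `(i, j)` cell indices,
#'   or a data frame with columns `i`, `j` (and optionally `probe` labels).
#' @param probe_dt Uniform probe sampling interval, s.
#' @param monitors Optional named list of 2-column `(i, j)` index matrices.
#' @param threshold Overpressure threshold, Pa, for the monitors.
#' @param p_ambient Ambient pressure, Pa, subtracted to form overpressure.
#' @param snapshot_times Numeric vector of times, s, for pressure snapshots.
#' @param max_steps Step-count guard.
#' @return A list of class `waf_run`:
#' \describe{
#'   \item{field}{final `axi_field`}
#'   \item{traces}{tibble `(time_s, overpressure_pa, probe)`}
#'   \item{arrivals}{tibble `(monitor, time_s)` of first threshold crossings
#'     (`NA` when never crossed)}
#'   \item{snapshots}{list of `(time, pressure)` pairs (matrix, Pa)}
#'   \item{steps}{number of steps taken}
#' }
#' @export
run_axisymmetric <- function(field, grid, t_end, cfl = 0.4,
                             probes = NULL, probe_dt = 1e-5,
                             monitors = NULL, threshold = 5e3,
                             p_ambient = 101.3e3,
                             snapshot_times = numeric(0),
                             max_steps = 10000000L) {
  stopifnot(t_end > 0)
  probe_labels <- character(0)
  if (is.null(probes)) {
    pm <- matrix(integer(0), 0, 2)
    probe_dt_use <- 0
  } else {
    if (is.data.frame(probes)) {
      probe_labels <- if (!is.null(probes$probe)) as.character(probes$probe)
        else paste0("P", seq_len(nrow(probes)))
      pm <- cbind(probes$i, probes$j)
    } else {
      pm <- probes
      probe_labels <- if (!is.null(rownames(probes))) rownames(probes)
        else paste0("P", seq_len(nrow(probes)))
    }
    bad <- grid$mask[pm] != 0
    if (any(bad)) {
      stop("probes inside the solid mask: ",
           paste(probe_labels[bad], collapse = ", "))
    }
    pm <- pm - 1L  # 0-based for the C++ core
    probe_dt_use <- probe_dt
  }
  mon_list <- list()
  if (!is.null(monitors)) {
    mon_list <- lapply(monitors, function(m) {
      m <- as.matrix(m)
      storage.mode(m) <- "integer"
      m - 1L
    })
  }
  out <- run_axi_cpp(field$density, field$mom_z, field$mom_r, field$energy,
                     grid$mask, grid$dz, grid$dr, field$gamma, cfl, t_end,
                     grid$axisym, grid$bc, pm, probe_dt_use,
                     mon_list, threshold, p_ambient,
                     sort(snapshot_times), as.integer(max_steps))
  traces <- if (nrow(pm) > 0) {
    n_out <- length(out$probe_t)
    tibble::tibble(
      time_s = rep(out$probe_t, times = nrow(pm)),
      overpressure_pa = as.vector(out$probe_p) - p_ambient,
      probe = rep(probe_labels, each = n_out)
    )
  } else {
    tibble::tibble(time_s = numeric(0), overpressure_pa = numeric(0),
                   probe = character(0))
  }
  arrivals <- tibble::tibble(
    monitor = if (length(mon_list)) names(mon_list) else character(0),
    time_s = as.numeric(out$monitor_times)
  )
  snaps <- purrr::map2(as.numeric(out$snapshot_times), out$snapshot_fields,
                       function(t, p) list(time = t, pressure = p))
  structure(list(
    field = structure(list(density = out$density, mom_z = out$mom_z,
                           mom_r = out$mom_r, energy = out$energy,
                           gamma = field$gamma, time = out$time),
                      class = "axi_field"),
    traces = traces, arrivals = arrivals, snapshots = snaps,
    steps = out$steps
  ), class = "waf_run")
}

# ---------------------------------------------------------------------------
# 1D interface

#' One WAF update of a 1D row of conserved states
#'
#' Conservative TVD WAF update of the 1D Euler equations (with a passively
#' advected transverse velocity). Mostly used directly in verification
#' tests; [run_waf_1d()] wraps the time loop.
#'
#' @param U `3 x n` or `4 x n` matrix of conserved variables per cell:
#'   rows (density, momentum, \[transverse momentum,\] energy density).
#' @param dt,dx Time step (s) and cell size (m); `dt` must satisfy the CFL
#'   condition for the data.
#' @param gamma Heat-capacity ratio.
#' @param bc Length-2 character vector for the left/right boundary,
#'   `"reflective"` or `"transmissive"`.
#' @return Updated matrix, same shape as `U`.
#' @export
waf_update_1d <- function(U, dt, dx, gamma = 1.4,
                          bc = c("transmissive", "transmissive")) {
  three <- nrow(U) == 3
  if (three) U <- rbind(U[1, ], U[2, ], 0, U[3, ])
  codes <- match(match.arg(bc, c("reflective", "transmissive"),
                           several.ok = TRUE),
                 c("reflective", "transmissive")) - 1L
  out <- waf_update_1d_cpp(U, dt, dx, gamma, codes[1], codes[2])
  if (three) out[-3, , drop = FALSE] else out
}

#' Run the 1D WAF solver on an interval
#'
#' @param density,velocity,pressure Initial primitive fields: numeric
#'   vectors of length `n` (cell averages).
#' @param dx Cell size, m.
#' @param t_end End time, s.
#' @param gamma Heat-capacity ratio.
#' @param cfl Courant number.
#' @param bc Length-2 boundary conditions as in [waf_update_1d()].
#' @return A list with the final `density`, `velocity`, `pressure` vectors,
#'   cell centers `x`, the reached `time` and the step count.
#' @export
run_waf_1d <- function(density, velocity, pressure, dx, t_end,
                       gamma = 1.4, cfl = 0.4,
                       bc = c("transmissive", "transmissive")) {
  n <- length(density)
  stopifnot(length(velocity) == n, length(pressure) == n, t_end > 0)
  U <- rbind(density, density * velocity, 0,
             pressure / (gamma - 1) + 0.5 * density * velocity^2)
  codes <- match(match.arg(bc, c("reflective", "transmissive"),
                           several.ok = TRUE),
                 c("reflective", "transmissive")) - 1L
  t <- 0; step <- 0L
  while (t < t_end) {
    dt <- cfl * dx / max_signal_speed_1d(U, gamma)
    if (step < 5L) dt <- dt * 0.2
    if (t + dt > t_end) dt <- t_end - t
    U <- waf_update_1d_cpp(U, dt, dx, gamma, codes[1], codes[2])
    t <- t + dt
    step <- step + 1L
  }
  rho <- U[1, ]; u <- U[2, ] / rho
  p <- (gamma - 1) * (U[4, ] - 0.5 * (U[2, ]^2 + U[3, ]^2) / rho)
  list(x = (seq_len(n) - 0.5) * dx, density = rho, velocity = u,
       pressure = p, time = t, steps = step)
}
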