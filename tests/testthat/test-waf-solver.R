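sod_run <- function(n, t_end = 0.25, cfl = 0.4) {
  half <- n / 2
  run_waf_1d(density = c(rep(1, half), rep(0.125, half)),
             velocity = rep(0, n),
             pressure = c(rep(1, half), rep(0.1, half)),
             dx = 1 / n, t_end = t_end, cfl = cfl)
}

test_that("uniform states are preserved to machine precision", {
  U <- rbind(rep(1.2, 50), rep(1.2 * 30, 50), rep(2e5, 50))
  out <- waf_update_1d(U, dt = 1e-5, dx = 0.01)
  expect_equal(out, U, tolerance = 1e-14)

  # 2D: uniform axisymmetric field unchanged (geometric source balance)
  g <- axi_grid(20, 15, 0.01, axisym = TRUE)
  f <- axi_field(g, density = 1.2, pressure = 101.3e3)
  f2 <- advance(f, g, dt = 1e-6)
  expect_equal(f2$density, f$density, tolerance = 1e-13)
  expect_equal(f2$mom_r, f$mom_r, tolerance = 1e-6)
  expect_equal(f2$energy, f$energy, tolerance = 1e-13)
})

test_that("Sod problem converges to the exact solution", {
  errs <- vapply(c(100, 200, 400), function(n) {
    r <- sod_run(n)
    ex <- sod_reference(r$x, 0.25)
    mean(abs(r$density - ex$density))
  }, numeric(1))
  expect_lt(errs[[3]], 0.01)          # 400-cell benchmark bound
  expect_true(all(diff(errs) < 0))    # monotone grid convergence
})

test_that("a single shock initialized from the jump relations tracks Ms*a1", {
  gas <- gas_state()
  Ms <- 1.859
  s <- shock_from_mach(Ms, gas)
  n <- 800; dx <- 0.01
  x <- (seq_len(n) - 0.5) * dx
  x0 <- 1.0
  post <- x < x0
  r <- run_waf_1d(
    density = ifelse(post, gas$density * s$rho_ratio, gas$density),
    velocity = ifelse(post, s$u2, 0),
    pressure = ifelse(post, gas$pressure * s$p_ratio, gas$pressure),
    dx = dx, t_end = 8e-3
  )
  # locate the front as the overpressure half-rise point
  thr <- gas$pressure * (1 + s$p_ratio) / 2
  front <- max(x[r$pressure > thr])
  speed <- (front - x0) / r$time
  expect_equal(speed, Ms * gas$sound_speed, tolerance = 0.01)
})

test_that("mass and energy are conserved in a closed axisymmetric box", {
  n <- 40
  g <- axi_grid(n, 24, 0.01, axisym = TRUE)
  zc <- g$z_centers; rc <- g$r_centers
  pr <- outer(zc, rc, function(z, r)
    101.3e3 * (1 + 1.5 * exp(-((z - 0.2)^2 + r^2) / 0.002)))
  f <- axi_field(g, density = pr / (287 * 293), pressure = pr)
  t0 <- field_totals(f, g)
  for (k in 1:1000) {
    dt <- cfl_time_step(f, g)
    f <- advance(f, g, dt, r_first = (k %% 2 == 0))
  }
  t1 <- field_totals(f, g)
  expect_lt(abs(t1[["mass"]] - t0[["mass"]]) / t0[["mass"]], 1e-10)
  expect_lt(abs(t1[["energy"]] - t0[["energy"]]) / t0[["energy"]], 1e-10)
})

test_that("axis-centered pulses stay mirror-symmetric in z", {
  n <- 60
  g <- axi_grid(n, 30, 0.01, axisym = TRUE)
  zc <- g$z_centers; rc <- g$r_centers
  z0 <- n / 2 * 0.01  # mirror plane on a cell interface
  pr <- outer(zc, rc, function(z, r)
    101.3e3 * (1 + 2 * exp(-((z - z0)^2 + r^2) / 0.003)))
  f <- axi_field(g, density = pr / (287 * 293), pressure = pr)
  for (k in 1:300) {
    dt <- cfl_time_step(f, g)
    f <- advance(f, g, dt, r_first = (k %% 2 == 0))
  }
  p <- primitives(f, g)$pressure
  lo <- (n / 2):1; hi <- (n / 2 + 1):n
  asym <- max(abs(p[hi, ] - p[lo, ])) / 101.3e3
  expect_lt(asym, 1e-6)
})

test_that("r-invariant planar data degenerates to the 1D scheme", {
  n <- 80
  g <- axi_grid(n, 8, 1 / n, axisym = FALSE,
                bc = c("transmissive", "transmissive", "reflective",
                       "reflective"))
  half <- n / 2
  rho <- matrix(rep(c(rep(1, half), rep(0.125, half)), 8), n, 8)
  p <- matrix(rep(c(rep(1, half), rep(0.1, half)), 8), n, 8)
  f <- axi_field(g, density = rho, pressure = p)

  U <- rbind(rho[, 1], 0, 0, p[, 1] / 0.4)
  dt <- 0.3 * cfl_time_step(f, g)
  for (k in 1:20) {
    f <- advance(f, g, dt)  # z sweep then r sweep; r sweep is a no-op here
    U <- waf_update_1d(U, dt, 1 / n)
  }
  expect_equal(f$density[, 4], U[1, ], tolerance = 1e-12)
  expect_equal(f$mom_z[, 4], U[2, ], tolerance = 1e-12)
  expect_equal(f$energy[, 4], U[4, ], tolerance = 1e-12)
  # all rows identical (the r sweep introduced nothing)
  expect_equal(f$density[, 7], f$density[, 1], tolerance = 1e-14)
})

test_that("reflected shock pressure at a closed end matches the analytic ratio", {
  gas <- gas_state()
  Ms <- 1.859
  s <- shock_from_mach(Ms, gas)
  n <- 600; dx <- 0.005
  x <- (seq_len(n) - 0.5) * dx
  post <- x < 1.0
  # right-moving shock into quiescent gas, reflecting off the right wall
  t_hit <- (3 - 1) / (Ms * gas$sound_speed)
  r <- run_waf_1d(
    density = ifelse(post, gas$density * s$rho_ratio, gas$density),
    velocity = ifelse(post, s$u2, 0),
    pressure = ifelse(post, gas$pressure * s$p_ratio, gas$pressure),
    dx = dx, t_end = t_hit + 1.2e-3,
    bc = c("transmissive", "reflective")
  )
  p_wall <- r$pressure[n]
  p5_expected <- gas$pressure * s$p_ratio *
    reflected_pressure_ratio(s$p_ratio)
  expect_equal(p_wall, p5_expected, tolerance = 0.02)
})

test_that("positivity failures and probe placement are reported", {
  # kinetic energy exceeds total energy -> negative pressure in cell 1
  U <- rbind(c(1, 1), c(1, 0), c(0.4, 2.5))
  expect_error(waf_update_1d(U, dt = 1e-3, dx = 1e-3), "positivity")

  g <- axi_grid(10, 10, 0.01, mask = {
    m <- matrix(0L, 10, 10); m[5, 5] <- 1L; m
  })
  f <- axi_field(g, density = 1.2, pressure = 101.3e3)
  expect_error(
    run_axisymmetric(f, g, t_end = 1e-5,
                     probes = data.frame(i = 5, j = 5, probe = "bad")),
    "solid"
  )
})
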