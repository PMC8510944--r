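test_that("the default domain reproduces the published dimensions", {
  gm <- tube_geometry()
  expect_equal(gm$total_length, 0.5 + 5.8 + 2.78)

  dom <- suppressWarnings(build_domain(gm, mesh = 0.02))
  expect_equal(dom$grid$nz * dom$grid$dz, 9.08)
  expect_equal(dom$grid$nr * dom$grid$dr, 1.40)

  # driver volume: sum of annular cell volumes initialised at P4
  g <- dom$grid
  p <- primitives(dom$field, g)$pressure
  w <- matrix(2 * pi * g$r_centers * g$dr * g$dz, g$nz, g$nr, byrow = TRUE)
  vol <- sum(w[p > 1e6 & !is.na(p)])
  expect_equal(vol, pi * 0.16^2 * 0.5, tolerance = 0.05)
})

test_that("the solid mask is watertight except through the nozzle", {
  dom <- suppressWarnings(build_domain(tube_geometry(), mesh = 0.02))
  g <- dom$grid
  fluid <- g$mask == 0
  # flood fill from the driver region
  reach <- matrix(FALSE, g$nz, g$nr)
  reach[1, 1] <- TRUE
  frontier <- matrix(c(1L, 1L), 1)
  while (nrow(frontier) > 0) {
    nxt <- NULL
    for (k in seq_len(nrow(frontier))) {
      i <- frontier[k, 1]; j <- frontier[k, 2]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= g$nz && jj >= 1 && jj <= g$nr &&
            fluid[ii, jj] && !reach[ii, jj]) {
          reach[ii, jj] <- TRUE
          nxt <- rbind(nxt, c(ii, jj))
        }
      }
    }
    frontier <- if (is.null(nxt)) matrix(integer(0), 0, 2) else nxt
  }
  # every fluid cell is reachable (single connected component through the
  # nozzle aperture) and no solid cell is
  expect_true(all(reach[fluid]))
  expect_false(any(reach[!fluid]))

  # the only fluid passage at the room interface plane is the tube bore:
  # just before the room the fluid column is the channel bore
  i_last_channel <- max(which(g$z_centers < 0.5 + 5.8))
  open_r <- g$r_centers[fluid[i_last_channel, ]]
  expect_lte(max(open_r), 0.16)
})

test_that("equilibrium initial conditions stay flat", {
  gm <- tube_geometry()
  cfg <- scenario_config(nominal_pressure = 3.0e6, mode = "nominal",
                         geometry = gm, mesh = 0.02, t_end = 2e-3)
  cfg$p4 <- cfg$p1  # equal pressures: no shock, no arrivals
  s <- suppressWarnings(simulate_scenario(cfg))
  expect_true(all(abs(s$traces$overpressure_pa) < 1e-6))
  expect_true(all(is.na(s$arrivals$time_s)))
})

test_that("effective driver pressure maps the calibrated operating point", {
  expect_equal(effective_driver_pressure(3.0e6), 2.3e6)
  expect_equal(effective_driver_pressure(3.0e6, "nominal"), 3.0e6)
  # proportional scaling convention for uncalibrated settings
  expect_equal(effective_driver_pressure(1.5e6), 1.15e6)
  expect_error(effective_driver_pressure(2.0e6), "unsupported")
})

test_that("probe layout lands in fluid and mesh misfit is caught", {
  gm <- tube_geometry()
  pr <- default_probes(gm, mesh = 0.02)
  dom <- suppressWarnings(build_domain(gm, mesh = 0.02))
  expect_true(all(dom$grid$mask[cbind(pr$i, pr$j)] == 0))
  expect_error(build_domain(gm, mesh = 0.03), "mesh")
  expect_warning(build_domain(gm, mesh = 0.02), "thinner")
})

test_that("confinement raises late-time room pressure over an open boundary", {
  # closed room: reflected waves accumulate; open far boundary vents them.
  # The first-wave peak at the wall is identical by construction, so the
  # confinement effect is measured as the late-time room-mean overpressure.
  mean_room_op <- function(open) {
    cfg <- scenario_config(mesh = 0.02, t_after_t0 = 10e-3,
                           snapshot_offsets_ms = 10, open_room = open)
    s <- suppressWarnings(simulate_scenario(cfg))
    sn <- s$snapshots[[1]]
    zc <- (seq_len(nrow(sn$pressure)) - 0.5) * 0.02
    mean(sn$pressure[zc > 6.3, ] - 101.3e3, na.rm = TRUE)
  }
  closed <- mean_room_op(FALSE)
  open <- mean_room_op(TRUE)
  expect_gt(closed, open)
  expect_gt(closed, 0)
})

test_that("channel probe traces show the sharp rise and quasi-plateau", {
  cfg <- scenario_config(mesh = 0.02, t_after_t0 = 1e-3)
  s <- suppressWarnings(simulate_scenario(cfg))
  tr <- s$traces[s$traces$probe == "PT4", ]
  m <- trace_metrics(tr, threshold = 5e3)
  expect_true(m$arrived)
  # incident overpressure close to the jump-relation value at Ms ~ 1.87
  gas <- gas_state()
  ms <- mach_from_p4p1(2.3e6 / 101.3e3)
  expected_op <- (shock_from_mach(ms, gas)$p_ratio - 1) * 101.3e3
  expect_equal(m$peak_pa, expected_op, tolerance = 0.08)
  # quasi-plateau: shortly after arrival the trace stays near the jump value
  post <- tr[tr$time_s > m$arrival_s + 2e-4 &
               tr$time_s < m$arrival_s + 1.2e-3, ]
  expect_true(all(post$overpressure_pa > 0.6 * m$peak_pa))
})
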