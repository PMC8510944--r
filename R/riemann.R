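#' Exact solution of the 1D Euler Riemann problem
#'
#' Solves the two-wave pressure function for the star-region pressure by
#' Newton iteration (two-shock / two-rarefaction connective functions), then
#' exposes the full self-similar solution for sampling. Used as the flux
#' oracle for the finite-volume solver and available as a solver in its own
#' right.
#'
#' @param left,right Primitive states, numeric vectors `c(density, velocity,
#'   pressure)` (kg/m^3, m/s, Pa).
#' @param gamma Heat-capacity ratio.
#' @param tol Relative residual tolerance for the star-pressure iteration.
#' @return An object of class `riemann_solution`: list with `p_star`,
#'   `u_star`, `left_wave` and `right_wave` (`"shock"` or `"rarefaction"`),
#'   the input states and `gamma`.
#' @examples
#' sod <- riemann_exact(c(1, 0, 1), c(0.125, 0, 0.1), gamma = 1.4)
#' sod$p_star  # ~0.30313
#' @export
riemann_exact <- function(left, right, gamma = 1.4, tol = 1e-14) {
  stopifnot(length(left) == 3, length(right) == 3)
  rl <- left[1]; ul <- left[2]; pl <- left[3]
  rr <- right[1]; ur <- right[2]; pr <- right[3]
  if (rl <= 0 || rr <= 0 || pl <= 0 || pr <= 0) {
    stop("densities and pressures must be positive")
  }
  g <- gamma
  al <- sqrt(g * pl / rl)
  ar <- sqrt(g * pr / rr)

  # vacuum generation: pressure positivity condition
  if (2 / (g - 1) * (al + ar) <= ur - ul) {
    stop("vacuum is generated by these states: the two rarefactions separate")
  }

  # connective function f(p; state) and derivative
  fK <- function(p, rk, pk, ak) {
    if (p > pk) {                      # shock
      A <- 2 / ((g + 1) * rk)
      B <- (g - 1) / (g + 1) * pk
      f <- (p - pk) * sqrt(A / (p + B))
      df <- sqrt(A / (B + p)) * (1 - (p - pk) / (2 * (B + p)))
    } else {                           # rarefaction
      f <- 2 * ak / (g - 1) * ((p / pk)^((g - 1) / (2 * g)) - 1)
      df <- 1 / (rk * ak) * (p / pk)^(-(g + 1) / (2 * g))
    }
    c(f, df)
  }

  # initial guess: two-rarefaction approximation, guarded
  p_tr <- ((al + ar - 0.5 * (g - 1) * (ur - ul)) /
             (al / pl^((g - 1) / (2 * g)) + ar / pr^((g - 1) / (2 * g))))^
    (2 * g / (g - 1))
  p <- max(p_tr, 1e-12 * min(pl, pr))

  for (i in 1:100) {
    l <- fK(p, rl, pl, al)
    r <- fK(p, rr, pr, ar)
    f <- l[1] + r[1] + (ur - ul)
    df <- l[2] + r[2]
    dp <- f / df
    p_new <- p - dp
    if (p_new <= 0) p_new <- 0.5 * p
    if (abs(p_new - p) < tol * p_new) { p <- p_new; break }
    p <- p_new
  }
  u_star <- 0.5 * (ul + ur) +
    0.5 * (fK(p, rr, pr, ar)[1] - fK(p, rl, pl, al)[1])

  structure(list(
    p_star = p, u_star = u_star,
    left_wave = if (p > pl) "shock" else "rarefaction",
    right_wave = if (p > pr) "shock" else "rarefaction",
    left = c(density = rl, velocity = ul, pressure = pl),
    right = c(density = rr, velocity = ur, pressure = pr),
    gamma = g
  ), class = "riemann_solution")
}

#' @export
print.riemann_solution <- function(x, ...) {
  cat(sprintf(
    "<riemann_solution> p* = %.6g, u* = %.6g (%s-wave left, %s-wave right)\n",
    x$p_star, x$u_star, x$left_wave, x$right_wave
  ))
  invisible(x)
}

#' Sample an exact Riemann solution at similarity coordinates
#'
#' The solution is self-similar in \eqn{\xi = x/t}; this evaluates density,
#' velocity and pressure along a vector of \eqn{\xi}.
#'
#' @param solution A [riemann_exact()] result.
#' @param xi Similarity coordinates x/t (m/s), any numeric vector.
#' @return A tibble with columns `xi`, `density`, `velocity`, `pressure`.
#' @export
riemann_sample <- function(solution, xi) {
  g <- solution$gamma
  rl <- solution$left[["density"]];  ul <- solution$left[["velocity"]]
  pl <- solution$left[["pressure"]]
  rr <- solution$right[["density"]]; ur <- solution$right[["velocity"]]
  pr <- solution$right[["pressure"]]
  ps <- solution$p_star; us <- solution$u_star
  al <- sqrt(g * pl / rl); ar <- sqrt(g * pr / rr)

  one <- function(s) {
    if (s <= us) {  # left of contact
      if (ps > pl) {  # left shock
        sl <- ul - al * sqrt((g + 1) / (2 * g) * ps / pl + (g - 1) / (2 * g))
        if (s <= sl) return(c(rl, ul, pl))
        rsl <- rl * ((ps / pl + (g - 1) / (g + 1)) /
                       ((g - 1) / (g + 1) * ps / pl + 1))
        return(c(rsl, us, ps))
      } else {        # left rarefaction
        shl <- ul - al
        asl <- al * (ps / pl)^((g - 1) / (2 * g))
        stl <- us - asl
        if (s <= shl) return(c(rl, ul, pl))
        if (s >= stl) return(c(rl * (ps / pl)^(1 / g), us, ps))
        u <- 2 / (g + 1) * (al + (g - 1) / 2 * ul + s)
        a <- 2 / (g + 1) * (al + (g - 1) / 2 * (ul - s))
        r <- rl * (a / al)^(2 / (g - 1))
        p <- pl * (a / al)^(2 * g / (g - 1))
        return(c(r, u, p))
      }
    } else {        # right of contact
      if (ps > pr) {  # right shock
        sr <- ur + ar * sqrt((g + 1) / (2 * g) * ps / pr + (g - 1) / (2 * g))
        if (s >= sr) return(c(rr, ur, pr))
        rsr <- rr * ((ps / pr + (g - 1) / (g + 1)) /
                       ((g - 1) / (g + 1) * ps / pr + 1))
        return(c(rsr, us, ps))
      } else {        # right rarefaction
        shr <- ur + ar
        asr <- ar * (ps / pr)^((g - 1) / (2 * g))
        str_ <- us + asr
        if (s >= shr) return(c(rr, ur, pr))
        if (s <= str_) return(c(rr * (ps / pr)^(1 / g), us, ps))
        u <- 2 / (g + 1) * (-ar + (g - 1) / 2 * ur + s)
        a <- 2 / (g + 1) * (ar - (g - 1) / 2 * (ur - s))
        r <- rr * (a / ar)^(2 / (g - 1))
        p <- pr * (a / ar)^(2 * g / (g - 1))
        return(c(r, u, p))
      }
    }
  }
  m <- t(vapply(xi, one, numeric(3)))
  tibble::tibble(xi = xi, density = m[, 1], velocity = m[, 2],
                 pressure = m[, 3])
}

#' HLLC approximate Riemann flux
#'
#' The Harten-Lax-van Leer-contact approximate flux for the 1D Euler
#' equations with a passively advected transverse velocity, as used inside
#' the WAF scheme. Wave speeds come from a pressure-based (PVRS-style)
#' estimate with direct bounds as fallback, robust for strong shocks.
#'
#' @param left,right Primitive states `c(density, velocity, pressure)` or
#'   length-4 `c(density, velocity, transverse_velocity, pressure)`.
#' @param gamma Heat-capacity ratio.
#' @return Numeric length-4 conserved-variable flux
#'   `(mass, normal momentum, transverse momentum, energy)`.
#' @export
hllc_flux <- function(left, right, gamma = 1.4) {
  pad <- function(w) if (length(w) == 3) c(w[1], w[2], 0, w[3]) else w
  l <- pad(left); r <- pad(right)
  if (any(c(l[1], l[4], r[1], r[4]) <= 0)) {
    stop("densities and pressures must be positive")
  }
  hllc_flux_cpp(l, r, gamma)
}

#' Exact physical Euler flux of a single state
#'
#' \eqn{F(U) = (\rho u,\ \rho u^2 + p,\ \rho u v,\ u(E + p))}. Used in
#' consistency checks of approximate fluxes.
#'
#' @inheritParams hllc_flux
#' @param state Primitive state, length 3 or 4 as in [hllc_flux()].
#' @return Numeric length-4 flux vector.
#' @export
euler_flux <- function(state, gamma = 1.4) {
  w <- if (length(state) == 3) c(state[1], state[2], 0, state[3]) else state
  rho <- w[1]; u <- w[2]; v <- w[3]; p <- w[4]
  E <- p / (gamma - 1) + 0.5 * rho * (u^2 + v^2)
  c(rho * u, rho * u^2 + p, rho * u * v, u * (E + p))
}
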