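#' Shock-front speed from the isentropic jump relation
#'
#' For weak compression fronts in a liquid the Rankine--Hugoniot jump can be
#' treated isentropically, giving
#' \deqn{c_s = \sqrt{\frac{\rho_1}{\rho_0}\,\frac{p_1 - p_0}{\rho_1 - \rho_0}}}
#' with the behind-front density taken on the acoustic isentrope through the
#' reference state. Reduces to c0 in the acoustic limit p1 -> p0 and is
#' monotone increasing in p1.
#'
#' @param fluid a [fluid_spec()].
#' @param p_behind absolute pressure behind the front (Pa); must be at least
#'   the ambient pressure (rarefaction fronts are rejected).
#' @param ambient absolute pressure ahead of the front (Pa); defaults to the
#'   fluid's p0.
#' @return Shock speed (m s^-1), >= c0.
#' @export
#' @examples
#' shock_speed_isentropic(water_spec(), 101325 + 3e6)  # a few m/s above c0
shock_speed_isentropic <- function(fluid, p_behind, ambient = fluid$p0) {
  stopifnot(inherits(fluid, "fluid_spec"))
  dp <- p_behind - ambient
  if (any(dp < 0))
    stop("rarefaction fronts are not supported (p_behind < ambient)")
  rho1 <- isentrope_density(fluid, dp)
  out <- sqrt((rho1 / fluid$rho0) * dp / (rho1 - fluid$rho0))
  # acoustic limit: 0/0 as dp -> 0; the limit is c0
  out[dp == 0] <- fluid$c0
  out
}

#' Particle velocity behind a weak shock front
#'
#' Returns both forms the weak-shock theory provides: the acoustic
#' approximation \eqn{u = \Delta p/(\rho_0 c_0)} (the Joukowsky relation) and
#' the exact mass-flux form \eqn{u = c_s (\rho_1 - \rho_0)/\rho_1} with the
#' front speed from [shock_speed_isentropic()].
#'
#' @inheritParams shock_speed_isentropic
#' @return Named numeric vector \code{c(acoustic = , exact = )} (m s^-1).
#' @export
particle_velocity <- function(fluid, p_behind, ambient = fluid$p0) {
  stopifnot(inherits(fluid, "fluid_spec"))
  dp <- p_behind - ambient
  if (any(dp < 0))
    stop("rarefaction fronts are not supported (p_behind < ambient)")
  cs <- shock_speed_isentropic(fluid, p_behind, ambient)
  rho1 <- isentrope_density(fluid, dp)
  c(acoustic = dp / (fluid$rho0 * fluid$c0),
    exact = cs * (rho1 - fluid$rho0) / rho1)
}

#' Shock-front speed from particle velocity (weak-shock expansion)
#'
#' The exact isentropic relation \eqn{c_s = c_0 (1 + \gamma u/c_0)^
#' {(\gamma-1)/(2\gamma)}} and its leading-order Taylor expansion
#' \eqn{c_s \approx c_0 + \frac{\gamma-1}{2} u}. Both are returned; their
#' difference is O(u^2).
#'
#' @param fluid a [fluid_spec()].
#' @param u particle velocity (m s^-1), nonnegative and small against c0.
#' @return Named numeric vector \code{c(exact = , linearized = )} (m s^-1).
#' @export
shock_speed_weak <- function(fluid, u) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (any(u < 0)) stop("particle velocity must be nonnegative")
  g <- fluid$gamma
  c(exact = fluid$c0 * (1 + g * u / fluid$c0)^((g - 1) / (2 * g)),
    linearized = fluid$c0 + (g - 1) / 2 * u)
}

#' Polytropic Hugoniot density ratio
#'
#' The classical polytropic-gas Hugoniot ratio
#' \deqn{\frac{\rho_1}{\rho_0} =
#'   \frac{(\gamma+1)p_1 + (\gamma-1)p_0}{(\gamma+1)p_0 + (\gamma-1)p_1}}
#' provided for completeness; the solver path uses the liquid (Tait) isentrope
#' forms instead.
#'
#' @param fluid a [fluid_spec()].
#' @param p_up,p_down absolute pressures ahead of / behind the front (Pa),
#'   both positive.
#' @return Dimensionless ratio; 1 when \code{p_up == p_down}.
#' @export
density_ratio <- function(fluid, p_up, p_down) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (any(p_up <= 0) || any(p_down <= 0)) stop("pressures must be positive")
  g <- fluid$gamma
  ((g + 1) * p_down + (g - 1) * p_up) / ((g + 1) * p_up + (g - 1) * p_down)
}

#' Construct a self-consistent weak-shock state
#'
#' Builds the laboratory-frame jump state for a compression front running
#' into fluid at rest: ahead state at ambient pressure with u = 0, behind
#' state from the isentropic jump relations.
#'
#' @inheritParams shock_speed_isentropic
#' @return An object of class \code{"shock_state"}: list with \code{p_up},
#'   \code{p_down} (absolute, Pa), \code{rho_up}, \code{rho_down},
#'   \code{u_up}, \code{u_down} and front speed \code{cs}.
#' @export
shock_state <- function(fluid, p_behind, ambient = fluid$p0) {
  stopifnot(inherits(fluid, "fluid_spec"))
  dp <- p_behind - ambient
  if (dp < 0) stop("rarefaction fronts are not supported")
  cs <- shock_speed_isentropic(fluid, p_behind, ambient)
  rho1 <- isentrope_density(fluid, dp)
  u1 <- cs * (rho1 - fluid$rho0) / rho1
  structure(list(p_up = ambient, p_down = p_behind,
                 rho_up = fluid$rho0, rho_down = rho1,
                 u_up = 0, u_down = u1, cs = cs),
            class = "shock_state")
}

#' Conservation residuals across a shock state
#'
#' Normalized residuals of the mass, momentum and Bernoulli (energy) balances
#' in the shock-fixed frame:
#' \itemize{
#'   \item mass: \eqn{\rho_0(u_0 - c_s) - \rho_1(u_1 - c_s)}, scaled by
#'     \eqn{\rho_0 c_s};
#'   \item momentum: \eqn{[p_0 + \rho_0(u_0-c_s)^2] - [p_1 + \rho_1(u_1-c_s)^2]},
#'     scaled by \eqn{\rho_0 c_s^2} (the full balance, with the pressure terms);
#'   \item energy: enthalpy form
#'     \eqn{\tfrac12(u-c_s)^2 + \frac{\gamma}{\gamma-1}\frac{p + K/\gamma}{\rho}}
#'     difference across the front, scaled by \eqn{c_s^2/2}, using the
#'     effective liquid stiffness K/gamma consistent with the acoustic
#'     isentrope.
#' }
#' A uniform state gives exactly zero. States built by [shock_state()] give
#' machine-precision mass and momentum residuals (the isentropic front speed
#' of [shock_speed_isentropic()] conserves both exactly), while the energy
#' residual measures the entropy production the isentropic treatment
#' neglects and grows smoothly with the jump strength. Serves as the
#' conservation oracle in the test suite.
#'
#' @param state a [shock_state()].
#' @param fluid a [fluid_spec()].
#' @return Named numeric vector \code{c(mass = , momentum = , energy = )}.
#' @export
jump_residuals <- function(state, fluid) {
  stopifnot(inherits(state, "shock_state"), inherits(fluid, "fluid_spec"))
  g <- fluid$gamma
  Beff <- fluid$K / g
  w0 <- state$u_up - state$cs
  w1 <- state$u_down - state$cs
  mass <- (state$rho_up * w0 - state$rho_down * w1) / (state$rho_up * state$cs)
  mom <- ((state$p_up + state$rho_up * w0^2) -
          (state$p_down + state$rho_down * w1^2)) /
         (state$rho_up * state$cs^2)
  h0 <- 0.5 * w0^2 + g / (g - 1) * (state$p_up + Beff) / state$rho_up
  h1 <- 0.5 * w1^2 + g / (g - 1) * (state$p_down + Beff) / state$rho_down
  energy <- (h0 - h1) / (0.5 * state$cs^2)
  c(mass = mass, momentum = mom, energy = energy)
}

#' @export
print.shock_state <- function(x, ...) {
  cat("Weak-shock jump state (laboratory frame)\n")
  cat(sprintf("  ahead : p = %.6g Pa, rho = %.4f kg/m^3, u = %.4g m/s\n",
              x$p_up, x$rho_up, x$u_up))
  cat(sprintf("  behind: p = %.6g Pa, rho = %.4f kg/m^3, u = %.4g m/s\n",
              x$p_down, x$rho_down, x$u_down))
  cat(sprintf("  front speed cs = %.2f m/s\n", x$cs))
  invisible(x)
}
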