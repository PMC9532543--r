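#' Solid material
#'
#' Wall / projectile material constants: density, longitudinal wave speed and
#' elastic moduli.
#'
#' @param rho_s density (kg m^-3).
#' @param c_s longitudinal (bulk) wave speed (m s^-1), used for the 1D
#'   acoustic impedance rho_s * c_s.
#' @param E elastic (Young's) modulus (Pa).
#' @param G shear modulus (Pa).
#' @param name optional label.
#' @return An object of class \code{"solid_material"}.
#' @seealso [material_preset()] for PMMA, steel and borosilicate glass.
#' @export
solid_material <- function(rho_s, c_s, E, G, name = "custom") {
  vals <- c(rho_s = rho_s, c_s = c_s, E = E, G = G)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all material parameters must be finite and strictly positive")
  structure(list(rho_s = rho_s, c_s = c_s, E = E, G = G, name = name),
            class = "solid_material")
}

#' Handbook material presets
#'
#' Standard handbook values for the materials used by the packaged cases:
#' PMMA (rho = 1180 kg m^-3, c = 2757 m s^-1), steel (7850, 5900) and
#' borosilicate glass (2230, 5640). All values are overridable by building a
#' [solid_material()] directly.
#'
#' @param name one of \code{"pmma"}, \code{"steel"}, \code{"glass"}.
#' @return A \code{"solid_material"}.
#' @export
material_preset <- function(name = c("pmma", "steel", "glass")) {
  name <- match.arg(tolower(name), c("pmma", "steel", "glass"))
  switch(name,
    pmma = solid_material(1180, 2757, E = 3.3e9, G = 1.2e9, name = "pmma"),
    steel = solid_material(7850, 5900, E = 200e9, G = 79.3e9, name = "steel"),
    glass = solid_material(2230, 5640, E = 63e9, G = 26.2e9, name = "glass"))
}

#' @export
print.solid_material <- function(x, ...) {
  cat(sprintf("Solid material '%s': rho = %.0f kg/m^3, c = %.0f m/s, E = %.3g Pa, G = %.3g Pa\n",
              x$name, x$rho_s, x$c_s, x$E, x$G))
  invisible(x)
}

#' Projectile specification
#'
#' Geometry, mass and impact velocity of the projectile. When \code{mass} is
#' omitted it is derived as rho_s * length * area.
#'
#' @param material a [solid_material()].
#' @param length projectile length (m).
#' @param area impact cross-section area (m^2); usually the channel bore area.
#' @param velocity impact velocity up (m s^-1), nonnegative.
#' @param mass projectile mass (kg); derived from the material and geometry
#'   when \code{NULL}.
#' @return An object of class \code{"projectile_spec"}.
#' @export
projectile_spec <- function(material, length, area, velocity, mass = NULL) {
  stopifnot(inherits(material, "solid_material"))
  if (length <= 0 || area <= 0) stop("length and area must be positive")
  if (velocity < 0) stop("impact velocity must be nonnegative")
  if (is.null(mass)) mass <- material$rho_s * length * area
  if (mass <= 0) stop("projectile mass must be positive")
  structure(list(material = material, length = length, area = area,
                 mass = mass, velocity = velocity),
            class = "projectile_spec")
}

#' @export
print.projectile_spec <- function(x, ...) {
  cat(sprintf("Projectile: %s, L = %.4g m, A = %.4g m^2, m = %.4g kg, up = %.3g m/s\n",
              x$material$name, x$length, x$area, x$mass, x$velocity))
  invisible(x)
}

#' Acoustic impedance
#'
#' The rho*c product of a medium: \code{rho_s * c_s} for a solid,
#' \code{rho0 * c0} for a liquid.
#'
#' @param x a [solid_material()] or [fluid_spec()].
#' @return Impedance (Pa s m^-1).
#' @export
impedance <- function(x) UseMethod("impedance")

#' @export
impedance.solid_material <- function(x) x$rho_s * x$c_s

#' @export
impedance.fluid_spec <- function(x) x$rho0 * x$c0

#' Impedance-matched impact amplitude
#'
#' Pressure--velocity matching at the projectile/fluid interface gives the
#' initial amplitude of the impact-generated front:
#' \deqn{\Delta p = \frac{Z_f Z_p}{Z_f + Z_p}\, u_p}
#' with Z the rho*c impedances. As the projectile impedance grows large this
#' reduces to the Joukowsky value \eqn{Z_f u_p}, always an upper bound.
#'
#' @param fluid a [fluid_spec()].
#' @param proj a [projectile_spec()].
#' @return Amplitude (Pa, gauge).
#' @export
#' @examples
#' pr <- projectile_spec(material_preset("pmma"), 0.01, 9e-6, velocity = 1)
#' matched_amplitude(water_spec(), pr)  # ~1.0 MPa
matched_amplitude <- function(fluid, proj) {
  stopifnot(inherits(fluid, "fluid_spec"), inherits(proj, "projectile_spec"))
  Zf <- impedance(fluid)
  Zp <- impedance(proj$material)
  Zf * Zp / (Zf + Zp) * proj$velocity
}

#' Decay constant of the impact pulse
#'
#' The projectile decelerates against the pressure it generates; with the
#' linearized isentropic slope at normal conditions the momentum balance
#' becomes a linear ODE whose rate is
#' \deqn{\lambda = \frac{\gamma - 1}{2}\,\frac{A_p}{m_p}\,
#'       \left(\frac{\partial p}{\partial c}\right)_s.}
#' Independent of the impact velocity; inversely proportional to projectile
#' mass (hence length at fixed section).
#'
#' @inheritParams matched_amplitude
#' @return Decay rate lambda (s^-1).
#' @export
decay_constant <- function(fluid, proj) {
  stopifnot(inherits(fluid, "fluid_spec"), inherits(proj, "projectile_spec"))
  if (proj$mass <= 0) stop("projectile mass must be positive")
  (fluid$gamma - 1) / 2 * (proj$area / proj$mass) * dp_dc_isentropic(fluid)
}

#' Impact-generated inlet pulse
#'
#' The exponential source pulse \eqn{p(t) = p(0)\,e^{-\lambda t}} (gauge) with
#' amplitude from [matched_amplitude()] and rate from [decay_constant()].
#'
#' @inheritParams matched_amplitude
#' @return An object of class \code{"source_pulse"}: list with \code{p_peak}
#'   (Pa, gauge), \code{lam} (s^-1) and \code{ambient} (Pa, absolute).
#' @seealso [pulse_pressure()] to evaluate it; [integrate_projectile_ode()]
#'   for the step-by-step deceleration integration it summarises.
#' @export
impact_pulse <- function(fluid, proj) {
  p0g <- matched_amplitude(fluid, proj)
  lam <- decay_constant(fluid, proj)
  structure(list(p_peak = p0g, lam = lam, ambient = fluid$p0),
            class = "source_pulse")
}

#' Evaluate a source pulse
#'
#' @param pulse a [impact_pulse()] result.
#' @param t time since impact (s), nonnegative; vectorised.
#' @param total if \code{TRUE} add the ambient offset (absolute pressure);
#'   default gauge.
#' @return Pressure (Pa).
#' @export
pulse_pressure <- function(pulse, t, total = FALSE) {
  stopifnot(inherits(pulse, "source_pulse"))
  if (any(t < 0)) stop("time must be nonnegative")
  pulse$p_peak * exp(-pulse$lam * t) + if (total) pulse$ambient else 0
}

#' @export
predict.source_pulse <- function(object, t, ...) pulse_pressure(object, t, ...)

#' @export
print.source_pulse <- function(x, ...) {
  cat(sprintf("Impact pulse: p(t) = %.4g Pa * exp(-%.4g t)  (gauge; ambient %.0f Pa)\n",
              x$p_peak, x$lam, x$ambient))
  cat(sprintf("  decay time 1/lambda = %.3g s\n", 1 / x$lam))
  invisible(x)
}

#' Explicit integration of the projectile deceleration
#'
#' Step-by-step integration (classical RK4) of the projectile momentum
#' balance \eqn{m_p\,\dot u_p = -p_i A_p} coupled to the linearized
#' pressure--velocity relation
#' \eqn{p_i = \frac{\gamma-1}{2}(\partial p/\partial c)_s\, u_p}.
#' This is the discrete process that the closed-form exponential pulse
#' summarises, and serves as its independent oracle in the test suite.
#'
#' @inheritParams matched_amplitude
#' @param t_end integration horizon (s).
#' @param dt time step (s), positive.
#' @return A data.frame with columns \code{t}, \code{u} (interface velocity,
#'   m s^-1) and \code{p} (interface gauge pressure, Pa).
#' @export
integrate_projectile_ode <- function(fluid, proj, t_end, dt) {
  stopifnot(inherits(fluid, "fluid_spec"), inherits(proj, "projectile_spec"))
  if (dt <= 0) stop("dt must be positive")
  k <- (fluid$gamma - 1) / 2 * dp_dc_isentropic(fluid)  # p = k * u
  rate <- k * proj$area / proj$mass                     # du/dt = -rate * u
  n <- max(1L, ceiling(t_end / dt))
  t <- seq(0, by = dt, length.out = n + 1L)
  u <- numeric(n + 1L)
  u[1L] <- proj$velocity
  for (i in seq_len(n)) {
    ui <- u[i]
    k1 <- -rate * ui
    k2 <- -rate * (ui + dt / 2 * k1)
    k3 <- -rate * (ui + dt / 2 * k2)
    k4 <- -rate * (ui + dt * k3)
    u[i + 1L] <- ui + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  data.frame(t = t, u = u, p = k * u)
}
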