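#' Liquid specification (Tait equation of state)
#'
#' Bundles the thermodynamic and transport constants of the working liquid.
#' Pressures in the EOS layer are measured on the Tait datum (p = 0 at the
#' reference density \code{rho0}); the ambient (absolute) offset \code{p0} is
#' carried alongside and applied by the solver and the reporting layer, so
#' that exported fields are total pressures.
#'
#' The bulk modulus is always derived as \code{K = rho0 * c0^2}; it is not an
#' independent input. Note that for real water the empirical Tait constants
#' (\code{B}, \code{gamma}) and the measured sound speed are not exactly
#' consistent (\code{sqrt(gamma*B/rho0) != c0} by a few percent); this package
#' treats \code{rho0}, \code{c0}, \code{gamma} and \code{B} as independent
#' givens, uses (\code{B}, \code{gamma}) for the pressure--density relation
#' and anchors all wave-speed quantities at (\code{rho0}, \code{c0}). See the
#' package vignette.
#'
#' @param rho0 reference density (kg m^-3).
#' @param c0 reference sound speed (m s^-1).
#' @param mu dynamic viscosity (Pa s).
#' @param B Tait pressure constant (Pa).
#' @param gamma Tait adiabatic exponent (dimensionless, > 1).
#' @param p0 ambient (absolute) reference pressure (Pa).
#'
#' @return An object of class \code{"fluid_spec"}: a list with the six inputs
#'   plus the derived bulk modulus \code{K}.
#' @seealso [water_spec()] for the packaged water preset.
#' @export
#' @examples
#' w <- water_spec()
#' w$K / (w$rho0 * w$c0^2)  # exactly 1 by construction
fluid_spec <- function(rho0, c0, mu, B, gamma, p0) {
  vals <- c(rho0 = rho0, c0 = c0, mu = mu, B = B, gamma = gamma, p0 = p0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all fluid parameters must be finite and strictly positive")
  if (gamma <= 1) stop("Tait exponent 'gamma' must exceed 1")
  structure(list(rho0 = rho0, c0 = c0, mu = mu, B = B, gamma = gamma,
                 p0 = p0, K = rho0 * c0^2, nu = mu / rho0),
            class = "fluid_spec")
}

#' Water at normal conditions
#'
#' The packaged water preset: rho0 = 999.8 kg m^-3, c0 = 1439 m s^-1,
#' B = 3.35e8 Pa, gamma = 7.15, p0 = 101325 Pa, mu = 1.0e-3 Pa s.
#'
#' @return A \code{"fluid_spec"}.
#' @export
water_spec <- function() {
  fluid_spec(rho0 = 999.8, c0 = 1439, mu = 1.0e-3,
             B = 3.35e8, gamma = 7.15, p0 = 101325)
}

#' @export
print.fluid_spec <- function(x, ...) {
  cat("Liquid (Tait EOS)\n")
  cat(sprintf("  rho0 = %.1f kg/m^3, c0 = %.0f m/s, mu = %.3g Pa s\n",
              x$rho0, x$c0, x$mu))
  cat(sprintf("  B = %.3g Pa, gamma = %.2f, p0 = %.0f Pa\n", x$B, x$gamma, x$p0))
  cat(sprintf("  K = rho0*c0^2 = %.4g Pa\n", x$K))
  invisible(x)
}

#' Tait pressure from density
#'
#' Evaluates the Tait equation of state
#' \deqn{p = B\left[(\rho/\rho_0)^\gamma - 1\right]}
#' on the Tait datum (p = 0 at rho = rho0).
#'
#' @param fluid a [fluid_spec()].
#' @param rho density (kg m^-3), strictly positive.
#' @return Pressure (Pa, Tait datum). Vectorised over \code{rho}.
#' @export
#' @examples
#' tait_pressure(water_spec(), 1000.8)  # ~2.40 MPa
tait_pressure <- function(fluid, rho) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (any(rho <= 0)) stop("density must be strictly positive")
  fluid$B * ((rho / fluid$rho0)^fluid$gamma - 1)
}

#' Tait density from pressure
#'
#' Inverse of [tait_pressure()]:
#' \eqn{\rho = \rho_0 ((p + B)/B)^{1/\gamma}}, strictly increasing in p.
#'
#' @param fluid a [fluid_spec()].
#' @param p pressure (Pa, Tait datum); must exceed \code{-B}.
#' @return Density (kg m^-3). Vectorised over \code{p}.
#' @export
tait_density <- function(fluid, p) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (any(p <= -fluid$B)) stop("pressure must exceed -B (Tait domain)")
  fluid$rho0 * ((p + fluid$B) / fluid$B)^(1 / fluid$gamma)
}

#' Linearized (acoustic) density correction
#'
#' First-order density correction \eqn{\rho = \rho_0 + p/c_0^2}, valid for
#' |p| much smaller than the bulk modulus K. Agrees with [tait_density()] to
#' first order in p/K.
#'
#' @inheritParams tait_density
#' @return Density (kg m^-3).
#' @export
linearized_density <- function(fluid, p) {
  stopifnot(inherits(fluid, "fluid_spec"))
  fluid$rho0 + p / fluid$c0^2
}

#' Local isentropic sound speed
#'
#' Sound speed along the isentrope through the reference state, anchored at
#' (rho0, c0):
#' \deqn{c(\rho) = c_0 (\rho/\rho_0)^{(\gamma-1)/2}, \qquad
#'       c(p) = c_0 \left(\frac{p + B}{B}\right)^{(\gamma-1)/(2\gamma)}.}
#' Equals c0 exactly at the reference state and is monotone nondecreasing in
#' compression. Supply exactly one of \code{p} (Tait datum) or \code{rho}.
#'
#' @param fluid a [fluid_spec()].
#' @param p pressure (Pa, Tait datum), or \code{NULL}.
#' @param rho density (kg m^-3), or \code{NULL}.
#' @return Sound speed (m s^-1).
#' @export
local_sound_speed <- function(fluid, p = NULL, rho = NULL) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (is.null(p) == is.null(rho))
    stop("supply exactly one of 'p' or 'rho'")
  g <- fluid$gamma
  if (!is.null(rho)) {
    if (any(rho <= 0)) stop("density out of EOS domain")
    return(fluid$c0 * (rho / fluid$rho0)^((g - 1) / 2))
  }
  if (any(p <= -fluid$B)) stop("pressure out of EOS domain")
  fluid$c0 * ((p + fluid$B) / fluid$B)^((g - 1) / (2 * g))
}

#' Isentropic pressure--sound-speed slope at normal conditions
#'
#' The linearized slope
#' \deqn{(\partial p/\partial c)_s = \frac{2\gamma}{\gamma-1}\,
#'       \frac{p_0 + B}{c_0}}
#' evaluated at the ambient state, used by the projectile-deceleration model
#' to turn the momentum balance into a first-order linear ODE (and hence an
#' exponential inlet pulse).
#'
#' @param fluid a [fluid_spec()].
#' @return Slope (Pa per m s^-1), strictly positive.
#' @export
#' @examples
#' dp_dc_isentropic(water_spec())  # ~5.41e5 Pa s/m
dp_dc_isentropic <- function(fluid) {
  stopifnot(inherits(fluid, "fluid_spec"))
  g <- fluid$gamma
  (2 * g / (g - 1)) * (fluid$p0 + fluid$B) / fluid$c0
}

# Density on the acoustic isentrope anchored at (rho0, c0): effective Tait
# curve with modulus K/gamma, so that dp/drho -> c0^2 at the reference state
# (slope 1/K for rho/rho0 in overpressure). Used by the shock-jump relations,
# which must reduce exactly to the acoustic limit cs -> c0.
isentrope_density <- function(fluid, dp) {
  g <- fluid$gamma
  fluid$rho0 * (1 + g * dp / fluid$K)^(1 / g)
}
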