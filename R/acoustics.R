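#' Rectangular channel specification
#'
#' Geometry and wall material of the fluid-filled rectangular conduit in
#' which the cells are cultured.
#'
#' @param a long side of the cross-section (m); \code{a >= b}.
#' @param b short side of the cross-section (m).
#' @param e wall thickness (m).
#' @param l channel length (m).
#' @param wall a [solid_material()] for the channel wall.
#' @param delta_cell average height of cultured cells (m); report-only, the
#'   hydraulic model treats the wall as smooth.
#' @param cell_density qualitative seeding flag: \code{"none"},
#'   \code{"sparse"} or \code{"confluent"}; report-only.
#' @return An object of class \code{"channel_spec"}; the cross-section area
#'   \code{A = a*b} and hydraulic diameter are precomputed.
#' @export
channel_spec <- function(a, b, e, l, wall,
                         delta_cell = 1e-5,
                         cell_density = c("sparse", "none", "confluent")) {
  stopifnot(inherits(wall, "solid_material"))
  cell_density <- match.arg(cell_density)
  if (!(a >= b && b > 0)) stop("require a >= b > 0")
  if (e <= 0 || l <= 0) stop("wall thickness and length must be positive")
  structure(list(a = a, b = b, e = e, l = l, wall = wall,
                 A = a * b,
                 Dh = 4 * a * b / (2 * (a + b)),
                 delta_cell = delta_cell, cell_density = cell_density),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("Rectangular channel: %.3g x %.3g x %.3g m, wall %.3g m %s\n",
              x$a, x$b, x$l, x$e, x$wall$name))
  cat(sprintf("  A = %.3g m^2, Dh = %.3g m, cells: %s (h ~ %.1g m)\n",
              x$A, x$Dh, x$cell_density, x$delta_cell))
  invisible(x)
}

#' Wall-compliance factor of a thick-walled rectangular duct
#'
#' Compliance factor Phi(a, b) of a liquid-filled rectangular duct with
#' thick walls, entering the celerity equation through the grouping
#' \deqn{c_f = 1\Big/\sqrt{\rho\left(\frac1K +
#'       \frac{\Phi(a,b)}{a\,b\,E\,e^2}\right)}.}
#'
#' The factor is assembled from the per-wall area gain under unit internal
#' pressure: each of the four walls is treated as a uniformly loaded
#' fixed-fixed plate strip of span a or b and thickness e, with a bending
#' contribution (plate modulus E/(1 - nu^2), nu inferred from E and G) and a
#' Timoshenko shear contribution (shear area factor 5/6, modulus G):
#' \deqn{\frac{\delta A}{\delta p} = \frac{a^5 + b^5}{30\,E'\,e^3}
#'       + \frac{a^3 + b^3}{5\,G\,e}.}
#' By construction Phi is symmetric in a and b, decreases the compliance term
#' as e grows, and vanishes from the celerity as E, G grow (rigid limit).
#'
#' @param a,b cross-section sides (m), \code{a >= b > 0}.
#' @param e wall thickness (m).
#' @param wall a [solid_material()].
#' @return Dimensionless-grouped factor Phi such that the fractional area
#'   compliance is \code{Phi / (a*b*E*e^2)} (1/Pa when divided as shown).
#' @export
phi_thorley <- function(a, b, e, wall) {
  stopifnot(inherits(wall, "solid_material"))
  if (!(a >= b && b > 0) || e <= 0) stop("degenerate duct geometry")
  E <- wall$E; G <- wall$G
  nu <- E / (2 * G) - 1
  if (nu <= -1 || nu >= 0.5) nu <- 0.3   # guard against unphysical E/G pairs
  Eplate <- E / (1 - nu^2)
  dAdp <- (a^5 + b^5) / (30 * Eplate * e^3) +
          (a^3 + b^3) / (6 * (5 / 6) * G * e)
  # express through the printed grouping Phi/(a b E e^2)
  dAdp * E * e^2
}

#' General conduit celerity from an area compliance
#'
#' The cross-section-agnostic celerity
#' \deqn{c_f = 1\Big/\sqrt{\rho\left(\frac1K +
#'   \frac1A\frac{\delta A}{\delta p}\right)}}
#' for a given fractional area compliance. Reduces to c0 when the walls are
#' rigid (\code{dAdp_over_A = 0}).
#'
#' @param fluid a [fluid_spec()].
#' @param dAdp_over_A fractional area compliance (1/Pa), nonnegative.
#' @return Celerity (m s^-1), <= c0.
#' @export
celerity_general <- function(fluid, dAdp_over_A) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (any(dAdp_over_A < 0)) stop("area compliance must be nonnegative")
  1 / sqrt(fluid$rho0 * (1 / fluid$K + dAdp_over_A))
}

#' Pressure-wave celerity in a rectangular channel
#'
#' Evaluates [celerity_general()] with the rectangular-duct wall compliance
#' from [phi_thorley()].
#'
#' @param fluid a [fluid_spec()].
#' @param ch a [channel_spec()].
#' @return Celerity cf (m s^-1), below the free-fluid sound speed c0 and
#'   approaching it as the wall stiffens.
#' @export
celerity_rect <- function(fluid, ch) {
  stopifnot(inherits(ch, "channel_spec"))
  phi <- phi_thorley(ch$a, ch$b, ch$e, ch$wall)
  celerity_general(fluid, phi / (ch$a * ch$b * ch$wall$E * ch$e^2))
}

#' Corrected bulk modulus for a rigid-wall solver
#'
#' \eqn{K_{mod} = \rho_0 c_f^2}: the effective fluid modulus that makes a
#' rigid-wall model propagate at the compliant-wall celerity.
#'
#' @param fluid a [fluid_spec()].
#' @param cf celerity (m s^-1), positive.
#' @return Kmod (Pa).
#' @export
corrected_bulk_modulus <- function(fluid, cf) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (any(cf <= 0)) stop("celerity must be positive")
  fluid$rho0 * cf^2
}

#' Fluid loading (fluid--structure coupling strength)
#'
#' The dimensionless fluid-loading parameter
#' \deqn{\beta = \frac{c_f^2}{c_s^2}\,\frac{\rho_f}{\rho_s}\,\frac{2R}{e}}
#' with R the mean radius of the section. For the rectangular section R is
#' taken as the hydraulic-radius equivalent \code{a*b/(a+b)} (half the
#' hydraulic diameter). Small beta justifies treating the channel as rigid;
#' the flag threshold is beta < 0.1 and the raw value is always reported.
#'
#' @param fluid a [fluid_spec()].
#' @param ch a [channel_spec()].
#' @param cf celerity (m s^-1); computed via [celerity_rect()] when omitted.
#' @return Named list: \code{beta}, \code{R}, \code{rigid_ok}.
#' @export
fluid_loading <- function(fluid, ch, cf = NULL) {
  stopifnot(inherits(fluid, "fluid_spec"), inherits(ch, "channel_spec"))
  if (is.null(cf)) cf <- celerity_rect(fluid, ch)
  R <- ch$A / (ch$a + ch$b)  # = Dh/2
  beta <- (cf^2 / ch$wall$c_s^2) * (fluid$rho0 / ch$wall$rho_s) * (2 * R / ch$e)
  list(beta = beta, R = R, rigid_ok = beta < 0.1)
}

#' Knudsen number (continuum criterion)
#'
#' Kn = mean free path / characteristic length; the continuum Navier--Stokes
#' description with no-slip walls requires Kn < 0.001.
#'
#' @param l_char characteristic length (m), positive.
#' @param mean_free_path molecular mean free path (m), positive; for liquid
#'   water the packaged default elsewhere is 3e-10 m.
#' @return Named list: \code{Kn}, \code{continuum_ok}.
#' @export
knudsen <- function(l_char, mean_free_path) {
  if (any(l_char <= 0) || any(mean_free_path <= 0))
    stop("lengths must be positive")
  Kn <- mean_free_path / l_char
  list(Kn = Kn, continuum_ok = Kn < 0.001)
}

#' Grid design under the Courant criterion
#'
#' Builds the axial/temporal discretization for the 1D transient solve and
#' reports the Courant number \eqn{C = c_f \Delta t / \Delta z}. Supply
#' either \code{dt} directly or a \code{courant} target (then
#' \code{dt = courant * dz / cf}). Explicit propagation requires C <= 1;
#' C = 1 makes the characteristics land exactly on grid nodes.
#'
#' @param cf celerity (m s^-1).
#' @param l channel length (m).
#' @param total_time simulated time span (s).
#' @param dz axial element size (m).
#' @param dt time step (s), or \code{NULL} to derive from \code{courant}.
#' @param courant Courant target used when \code{dt} is \code{NULL}
#'   (default 1).
#' @return An object of class \code{"grid_spec"}: \code{dz}, \code{dt},
#'   \code{courant}, node/step counts \code{nz}, \code{nt}, and the echoed
#'   \code{cf}, \code{l}, \code{total_time}.
#' @export
#' @examples
#' design_grid(cf = 1439, l = 0.06, total_time = 4.2e-5,
#'             dz = 1e-4, dt = 0.7e-7)$courant  # ~1.007
design_grid <- function(cf, l, total_time, dz, dt = NULL, courant = 1) {
  if (cf <= 0 || l <= 0 || total_time <= 0 || dz <= 0)
    stop("all grid inputs must be positive")
  if (is.null(dt)) dt <- courant * dz / cf
  if (dt <= 0) stop("dt must be positive")
  structure(list(dz = dz, dt = dt, courant = cf * dt / dz,
                 nz = as.integer(round(l / dz)),
                 nt = as.integer(round(total_time / dt)),
                 cf = cf, l = l, total_time = total_time),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Grid: dz = %.3g m (%d cells), dt = %.3g s (%d steps), Courant = %.4f\n",
              x$dz, x$nz, x$dt, x$nt, x$courant))
  invisible(x)
}

#' Channel acoustics and design-criteria report
#'
#' Evaluates the conduit-level acoustics and the design criteria in one
#' pass: celerity (compliant-wall or rigid), corrected bulk modulus, fluid
#' loading, and the continuum (Knudsen) check on the short side of the
#' section.
#'
#' @param fluid a [fluid_spec()].
#' @param ch a [channel_spec()].
#' @param mean_free_path liquid molecular mean free path (m); default 3e-10.
#' @param rigid if \code{TRUE} skip the wall-compliance correction and use
#'   cf = c0 (used when the wall properties are unknown but known-stiff).
#' @return An object of class \code{"acoustics_report"}: \code{cf},
#'   \code{Kmod}, \code{beta}, \code{R}, \code{Kn}, logical \code{rigid_ok},
#'   \code{continuum_ok}, and the inputs echoed.
#' @export
acoustics_report <- function(fluid, ch, mean_free_path = 3e-10,
                             rigid = FALSE) {
  cf <- if (rigid) fluid$c0 else celerity_rect(fluid, ch)
  fl <- fluid_loading(fluid, ch, cf)
  kn <- knudsen(ch$b, mean_free_path)
  structure(list(cf = cf, Kmod = corrected_bulk_modulus(fluid, cf),
                 beta = fl$beta, R = fl$R, Kn = kn$Kn,
                 rigid_ok = fl$rigid_ok, continuum_ok = kn$continuum_ok,
                 rigid_assumed = rigid, mean_free_path = mean_free_path),
            class = "acoustics_report")
}

#' @export
print.acoustics_report <- function(x, ...) {
  cat("Channel acoustics\n")
  cat(sprintf("  cf = %.2f m/s%s, Kmod = %.4g Pa\n", x$cf,
              if (x$rigid_assumed) " (rigid wall assumed)" else "", x$Kmod))
  cat(sprintf("  fluid loading beta = %.3g (rigid_ok: %s)\n",
              x$beta, x$rigid_ok))
  cat(sprintf("  Knudsen Kn = %.3g (continuum_ok: %s)\n",
              x$Kn, x$continuum_ok))
  invisible(x)
}
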