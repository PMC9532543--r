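# Laminar friction factor grouping f*Re for a rectangular duct
# (Shah & London polynomial in the aspect ratio alpha = b/a <= 1).
fRe_rect <- function(a, b) {
  al <- min(a, b) / max(a, b)
  96 * (1 - 1.3553 * al + 1.9467 * al^2 - 1.7012 * al^3 +
          0.9564 * al^4 - 0.2537 * al^5)
}

# Trikha three-exponential approximation of Zielke's laminar unsteady
# friction weighting kernel (circular-pipe kernel applied on the hydraulic
# radius; approximate for the rectangular section).
.trikha_m <- c(40.0, 8.1, 1.0)
.trikha_n <- c(8000, 200, 26.4)

#' 1D transient water-hammer solve (method of characteristics)
#'
#' Solves the linear rigid-wall water-hammer equations
#' \deqn{\partial_t p + \rho c_f^2\, \partial_z u = 0, \qquad
#'       \partial_t u + \tfrac1\rho \partial_z p = -\tfrac{F(u)}{\rho}}
#' on a fixed grid by the method of characteristics, with the impact pulse as
#' the inlet pressure boundary and either a constant-pressure or a closed
#' outlet. At Courant number 1 the characteristic feet coincide with grid
#' nodes and propagation is interpolation-free (exact for zero friction); at
#' C < 1 linear space-line interpolation is used. C > 1 is refused.
#'
#' Friction closures: \code{"none"}; \code{"quasi_steady"} laminar
#' (Poiseuille-equivalent for the rectangular section, f*Re from the Shah &
#' London aspect-ratio polynomial); \code{"unsteady"} adds Trikha's
#' three-exponential approximation of Zielke's laminar weighting kernel on
#' top of the quasi-steady term.
#'
#' @param fluid a [fluid_spec()].
#' @param ch a [channel_spec()].
#' @param pulse a [impact_pulse()] inlet boundary pulse.
#' @param grid a [design_grid()] discretization (its \code{cf} sets the
#'   propagation speed).
#' @param outlet \code{"constant_pressure"} (outlet held at ambient) or
#'   \code{"closed"} (zero velocity end wall).
#' @param friction \code{"quasi_steady"} (default), \code{"none"} or
#'   \code{"unsteady"}.
#' @return An object of class \code{"wave_field"}: list with node coordinates
#'   \code{z} (length nz+1), times \code{t} (length nt+1), matrices \code{p}
#'   (total pressure, Pa) and \code{u} (axial velocity, m s^-1) of dimension
#'   (nz+1) x (nt+1), and the run metadata (\code{cf}, \code{ambient},
#'   \code{outlet}, \code{friction}, the input specs).
#' @export
solve_transient <- function(fluid, ch, pulse, grid,
                            outlet = c("constant_pressure", "closed"),
                            friction = c("quasi_steady", "none", "unsteady")) {
  stopifnot(inherits(fluid, "fluid_spec"), inherits(ch, "channel_spec"),
            inherits(pulse, "source_pulse"), inherits(grid, "grid_spec"))
  outlet <- match.arg(outlet)
  friction <- match.arg(friction)
  C <- grid$courant
  if (C > 1 + 1e-9)
    stop(sprintf("Courant number %.4f exceeds 1: refusing to run (stability contract)", C))
  C <- min(C, 1)

  cf <- grid$cf
  Z <- fluid$rho0 * cf
  nz <- grid$nz; nt <- grid$nt
  dz <- grid$dz; dt <- grid$dt
  z <- seq(0, by = dz, length.out = nz + 1L)
  tt <- seq(0, by = dt, length.out = nt + 1L)
  amb <- pulse$ambient

  # quasi-steady laminar resistance: friction force per unit volume = Rlam*u
  Rlam <- if (friction == "none") 0 else
    fRe_rect(ch$a, ch$b) * fluid$mu / (2 * ch$Dh^2)

  use_unsteady <- friction == "unsteady"
  if (use_unsteady) {
    R0 <- ch$Dh / 2
    kdecay <- exp(-.trikha_n * fluid$nu * dt / R0^2)
    Y <- matrix(0, nrow = nz + 1L, ncol = 3L)   # kernel states per node
    cu <- 4 * fluid$rho0 * fluid$nu / R0^2      # force/volume per unit sum(Y)
  }

  p <- matrix(amb, nrow = nz + 1L, ncol = nt + 1L)
  u <- matrix(0, nrow = nz + 1L, ncol = nt + 1L)
  pcur <- rep(amb, nz + 1L)
  ucur <- rep(0, nz + 1L)

  idx <- 2:nz  # interior nodes
  for (n in seq_len(nt)) {
    # friction force per unit volume at current nodes
    Fcur <- Rlam * ucur
    if (use_unsteady) Fcur <- Fcur + cu * rowSums(Y)

    # characteristic foot values (space-line interpolation, exact at C = 1)
    pA <- pcur[idx] + C * (pcur[idx - 1L] - pcur[idx])
    uA <- ucur[idx] + C * (ucur[idx - 1L] - ucur[idx])
    fA <- Fcur[idx] + C * (Fcur[idx - 1L] - Fcur[idx])
    pB <- pcur[idx] + C * (pcur[idx + 1L] - pcur[idx])
    uB <- ucur[idx] + C * (ucur[idx + 1L] - ucur[idx])
    fB <- Fcur[idx] + C * (Fcur[idx + 1L] - Fcur[idx])

    CP <- pA + Z * uA - cf * dt * fA
    CM <- pB - Z * uB + cf * dt * fB

    pnew <- pcur; unew <- ucur
    pnew[idx] <- (CP + CM) / 2
    unew[idx] <- (CP - CM) / (2 * Z)

    # inlet: prescribed total pressure, u from the C- characteristic
    pnew[1L] <- amb + pulse_pressure(pulse, tt[n + 1L])
    pB1 <- pcur[1L] + C * (pcur[2L] - pcur[1L])
    uB1 <- ucur[1L] + C * (ucur[2L] - ucur[1L])
    fB1 <- Fcur[1L] + C * (Fcur[2L] - Fcur[1L])
    unew[1L] <- (pnew[1L] - (pB1 - Z * uB1 + cf * dt * fB1)) / Z

    # outlet from the C+ characteristic
    pAn <- pcur[nz + 1L] + C * (pcur[nz] - pcur[nz + 1L])
    uAn <- ucur[nz + 1L] + C * (ucur[nz] - ucur[nz + 1L])
    fAn <- Fcur[nz + 1L] + C * (Fcur[nz] - Fcur[nz + 1L])
    CPn <- pAn + Z * uAn - cf * dt * fAn
    if (outlet == "constant_pressure") {
      pnew[nz + 1L] <- amb
      unew[nz + 1L] <- (CPn - amb) / Z
    } else {
      unew[nz + 1L] <- 0
      pnew[nz + 1L] <- CPn
    }

    if (use_unsteady) {
      du <- unew - ucur
      Y <- sweep(Y, 2L, kdecay, `*`) + outer(du, .trikha_m)
    }

    pcur <- pnew; ucur <- unew
    p[, n + 1L] <- pnew
    u[, n + 1L] <- unew
  }

  structure(list(z = z, t = tt, p = p, u = u,
                 cf = cf, ambient = amb, outlet = outlet,
                 friction = friction,
                 fluid = fluid, channel = ch, pulse = pulse, grid = grid),
            class = "wave_field")
}

#' @export
print.wave_field <- function(x, ...) {
  cat(sprintf("Wave field: %d nodes x %d steps (dz = %.3g m, dt = %.3g s)\n",
              length(x$z), length(x$t), x$grid$dz, x$grid$dt))
  cat(sprintf("  cf = %.2f m/s, outlet = %s, friction = %s\n",
              x$cf, x$outlet, x$friction))
  cat(sprintf("  peak total pressure %.4g Pa, peak |u| %.3g m/s\n",
              max(x$p), max(abs(x$u))))
  invisible(x)
}

#' @export
summary.wave_field <- function(object, ...) {
  pk <- apply(object$p, 1L, max)
  out <- list(peak_pressure = max(object$p),
              peak_velocity = max(abs(object$u)),
              peak_by_z = data.frame(z = object$z, p_peak = pk),
              attenuation_per_15mm = tryCatch(
                peak_attenuation(object, 0.015), error = function(e) NA_real_))
  class(out) <- "summary.wave_field"
  out
}

#' @export
print.summary.wave_field <- function(x, ...) {
  cat(sprintf("Peak total pressure: %.4g Pa\n", x$peak_pressure))
  cat(sprintf("Peak axial velocity: %.4g m/s\n", x$peak_velocity))
  cat(sprintf("Mean peak-pressure reduction per 15 mm: %.3g%%\n",
              100 * x$attenuation_per_15mm))
  invisible(x)
}

#' @export
plot.wave_field <- function(x, positions = c(0.25, 0.5, 0.75),
                            what = c("pressure", "velocity"), ...) {
  what <- match.arg(what)
  i <- vapply(positions * x$grid$l,
              function(zp) which.min(abs(x$z - zp)), integer(1L))
  m <- if (what == "pressure") t(x$p[i, , drop = FALSE]) else
    t(x$u[i, , drop = FALSE])
  graphics::matplot(x$t * 1e6, m, type = "l", lty = 1,
                    xlab = "t (us)",
                    ylab = if (what == "pressure") "total pressure (Pa)"
                           else "axial velocity (m/s)", ...)
  graphics::legend("topright", legend = sprintf("z = %.2f l", positions),
                   col = seq_along(i), lty = 1, bty = "n")
  invisible(x)
}

#' Average peak-pressure attenuation per axial window
#'
#' Records the peak total pressure at the interior window boundaries
#' z = k * dz_window (excluding the outlet node, whose boundary condition
#' pins the pressure) and returns the mean relative drop between consecutive
#' boundaries.
#'
#' @param field a [solve_transient()] result.
#' @param dz_window window length (m); default 0.015 (a quarter of the
#'   packaged 60 mm channel).
#' @return Mean fractional reduction per window (dimensionless; multiply by
#'   100 for percent). Zero without friction.
#' @export
peak_attenuation <- function(field, dz_window = 0.015) {
  stopifnot(inherits(field, "wave_field"))
  l <- field$grid$l
  zb <- seq(dz_window, l - dz_window / 2, by = dz_window)
  if (length(zb) < 2L) stop("channel shorter than two windows")
  i <- vapply(zb, function(zp) which.min(abs(field$z - zp)), integer(1L))
  pk <- apply(field$p[i, , drop = FALSE], 1L, max)
  drops <- (pk[-length(pk)] - pk[-1L]) / pk[-length(pk)]
  mean(drops)
}

#' Monitor-point stress traces
#'
#' Samples the solved field at monitor positions (fractions of the channel
#' length; nearest grid node) and attaches the wall stress components: total
#' compression pressure, axial shear from the impulsively-started laminar
#' boundary layer ([stokes_layer_shear()]), and transverse shear, identically
#' zero in this planar 1D model.
#'
#' @param field a [solve_transient()] result.
#' @param positions monitor positions as fractions of channel length;
#'   default the canonical 0.25, 0.5, 0.75.
#' @param t_reg regularization time for the shear model (s); defaults to one
#'   solver step.
#' @return List of \code{"monitor_trace"} objects, each with \code{position}
#'   (m), \code{frac}, \code{t}, \code{p} (total, Pa), \code{tau_z} (Pa),
#'   \code{tau_x} (0), \code{delta} (boundary-layer thickness, m).
#' @export
monitor <- function(field, positions = c(0.25, 0.5, 0.75), t_reg = NULL) {
  stopifnot(inherits(field, "wave_field"))
  if (any(positions < 0 | positions > 1))
    stop("monitor positions must lie within the channel (fractions of l)")
  if (is.null(t_reg)) t_reg <- field$grid$dt
  lapply(positions, function(fr) {
    i <- which.min(abs(field$z - fr * field$grid$l))
    zi <- field$z[i]
    sh <- stokes_layer_shear(field$fluid, u_e = field$u[i, ], times = field$t,
                             t_arrival = zi / field$cf, t_reg = t_reg)
    structure(list(position = zi, frac = fr, t = field$t,
                   p = field$p[i, ], tau_z = sh$tau, tau_x = 0,
                   delta = sh$delta, t_reg = t_reg),
              class = "monitor_trace")
  })
}

#' @export
print.monitor_trace <- function(x, ...) {
  cat(sprintf("Monitor at z = %.4g m (%.2f l): peak p = %.4g Pa, peak tau_z = %.4g Pa\n",
              x$position, x$frac, max(x$p), max(x$tau_z)))
  invisible(x)
}

#' Export a wave field as a long-format data.frame
#'
#' @param x a [solve_transient()] result.
#' @param row.names,optional unused (S3 signature).
#' @param ... unused.
#' @return data.frame with columns \code{z_m}, \code{t_s}, \code{p_Pa},
#'   \code{u_m_s}.
#' @export
as.data.frame.wave_field <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(z_m = rep(x$z, times = length(x$t)),
             t_s = rep(x$t, each = length(x$z)),
             p_Pa = as.vector(x$p),
             u_m_s = as.vector(x$u))
}
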