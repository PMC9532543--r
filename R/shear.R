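#' Wall shear behind a traveling front (impulsively started boundary layer)
#'
#' Shear stress on the culture wall from the shock-induced laminar boundary
#' layer, modelled as the Stokes first problem driven by the local core
#' velocity: once the front arrives at a station the near-wall fluid is
#' impulsively set in motion, and the wall velocity gradient decays with the
#' elapsed time,
#' \deqn{\tau_z(t) = \frac{\mu\, u_e(t)}{\sqrt{\pi \nu\, (t - t_a + t_{reg})}},
#'   \qquad \delta(t) = \sqrt{\pi \nu\, (t - t_a + t_{reg})},}
#' where \eqn{t_a} is the front arrival time and \eqn{t_{reg}} regularizes
#' the t = 0 singularity (by default one solver time step; the peak shear is
#' sensitive to this choice, which is therefore reported with the trace).
#' Before arrival the shear is zero.
#'
#' @param fluid a [fluid_spec()].
#' @param u_e free-stream (core) axial velocity history at the station
#'   (m s^-1); zero before \code{t_arrival}.
#' @param times sample times (s), same length as \code{u_e}.
#' @param t_arrival front arrival time at the station (s).
#' @param t_reg regularization time (s), positive.
#' @return An object of class \code{"shear_trace"}: list with \code{t},
#'   \code{tau} (Pa), \code{delta} (m), \code{t_arrival}, \code{t_reg}.
#' @export
stokes_layer_shear <- function(fluid, u_e, times, t_arrival, t_reg) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (length(u_e) != length(times))
    stop("'u_e' and 'times' must have equal length")
  if (t_reg <= 0) stop("regularization time must be positive")
  elapsed <- times - t_arrival
  active <- elapsed >= 0
  delta <- rep(NA_real_, length(times))
  tau <- numeric(length(times))
  delta[active] <- sqrt(pi * fluid$nu * (elapsed[active] + t_reg))
  tau[active] <- fluid$mu * u_e[active] / delta[active]
  structure(list(t = times, tau = tau, delta = delta,
                 t_arrival = t_arrival, t_reg = t_reg),
            class = "shear_trace")
}

#' @export
print.shear_trace <- function(x, ...) {
  cat(sprintf("Shear trace: arrival %.3g s, t_reg %.3g s, peak tau_z = %.4g Pa\n",
              x$t_arrival, x$t_reg, max(x$tau)))
  invisible(x)
}

#' Wall stress components at a station
#'
#' Full wall stress decomposition at one axial position of a solved field:
#' the compressive normal stress (total pressure at the wall; the viscous
#' normal-stress correction 2 mu du/dz is evaluated behind the front and
#' reported, confirming it negligible), the axial shear from
#' [stokes_layer_shear()], and the transverse shear, identically zero by the
#' planar symmetry of the 1D model.
#'
#' @param fluid a [fluid_spec()].
#' @param field a [solve_transient()] result.
#' @param position axial position as a fraction of channel length, in [0, 1].
#' @param t_reg shear regularization time (s); default one solver step.
#' @return List with \code{sigma} (total pressure trace, Pa), \code{tau_z}
#'   (a \code{"shear_trace"}), \code{tau_x} (0), and
#'   \code{visc_normal_max} (Pa), the largest |2 mu du/dz| behind the front
#'   (the grid-limited jump cell itself is excluded, since there the gradient
#'   measures the discretization, not the flow).
#' @export
stress_components <- function(fluid, field, position, t_reg = NULL) {
  stopifnot(inherits(fluid, "fluid_spec"), inherits(field, "wave_field"))
  if (position < 0 || position > 1)
    stop("position must be a fraction of channel length in [0, 1]")
  if (is.null(t_reg)) t_reg <- field$grid$dt
  i <- which.min(abs(field$z - position * field$grid$l))
  zi <- field$z[i]
  sh <- stokes_layer_shear(fluid, u_e = field$u[i, ], times = field$t,
                           t_arrival = zi / field$cf, t_reg = t_reg)

  # viscous normal-stress correction behind the front: central-difference
  # du/dz at each time, masked to nodes the front passed at least 2 cells
  # ago; the scan covers the incident phase only (once the front reaches the
  # outlet the boundary reflection introduces a second grid-limited jump)
  nz <- length(field$z); nt <- length(field$t)
  dz <- field$grid$dz
  vmax <- 0
  front_node <- 1L + floor(field$t * field$cf / dz)
  for (n in seq_len(nt)) {
    if (front_node[n] >= nz) break
    jmax <- front_node[n] - 2L   # strictly behind the jump cell
    if (jmax < 3L) next
    j <- 2:(jmax - 1L)
    dudz <- (field$u[j + 1L, n] - field$u[j - 1L, n]) / (2 * dz)
    vmax <- max(vmax, 2 * fluid$mu * max(abs(dudz)))
  }
  list(sigma = field$p[i, ], tau_z = sh, tau_x = 0, visc_normal_max = vmax)
}
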