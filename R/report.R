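# -- configuration ----------------------------------------------------------

as_fluid <- function(x) {
  if (inherits(x, "fluid_spec")) return(x)
  if (is.character(x)) {
    if (tolower(x) != "water") stop("unknown fluid preset: ", x)
    return(water_spec())
  }
  do.call(fluid_spec, x[c("rho0", "c0", "mu", "B", "gamma", "p0")])
}

as_material <- function(x) {
  if (inherits(x, "solid_material")) return(x)
  if (is.character(x)) return(material_preset(x))
  do.call(solid_material, x[intersect(names(x),
                                      c("rho_s", "c_s", "E", "G", "name"))])
}

#' Assemble a validated run configuration
#'
#' Builds the full configuration for a design or simulation run from plain
#' values (as read from a YAML config file). All inputs are validated and
#' normalized here, before any computation; the resulting object is echoed
#' into every report for provenance.
#'
#' @param fluid \code{"water"}, a [fluid_spec()], or a named list of its
#'   fields.
#' @param projectile named list: \code{material} (preset name or fields),
#'   \code{length} (m), \code{velocity} (m s^-1), optional \code{area}
#'   (m^2, defaults to the channel bore area) and \code{mass} (kg).
#' @param channel named list: \code{a}, \code{b}, \code{e}, \code{l} (m) and
#'   \code{wall} (preset name or fields).
#' @param grid named list: \code{dz} (m), \code{total_time} (s), and either
#'   \code{dt} (s) or \code{courant} (target, default 1).
#' @param outlet \code{"constant_pressure"} or \code{"closed"}.
#' @param friction \code{"quasi_steady"}, \code{"none"} or \code{"unsteady"}.
#' @param celerity \code{"thorley"} (rectangular-duct wall-compliance
#'   correction) or \code{"rigid"} (cf = c0).
#' @param monitors monitor positions as fractions of channel length.
#' @param mean_free_path liquid mean free path (m) for the continuum check.
#' @param name run label.
#' @return An object of class \code{"run_config"}.
#' @seealso [read_run_config()], [preset_config()]
#' @export
run_config <- function(fluid = "water", projectile, channel, grid,
                       outlet = c("constant_pressure", "closed"),
                       friction = c("quasi_steady", "none", "unsteady"),
                       celerity = c("thorley", "rigid"),
                       monitors = c(0.25, 0.5, 0.75),
                       mean_free_path = 3e-10,
                       name = "run") {
  outlet <- match.arg(outlet)
  friction <- match.arg(friction)
  celerity <- match.arg(celerity)
  fl <- as_fluid(fluid)
  wall <- as_material(channel$wall)
  ch <- channel_spec(channel$a, channel$b, channel$e, channel$l, wall,
                     delta_cell = channel$delta_cell %||% 1e-5,
                     cell_density = channel$cell_density %||% "sparse")
  area <- projectile$area %||% ch$A
  proj <- projectile_spec(as_material(projectile$material),
                          length = projectile$length, area = area,
                          velocity = projectile$velocity,
                          mass = projectile$mass)
  if (is.null(grid$dz) || is.null(grid$total_time))
    stop("grid config requires 'dz' and 'total_time'")
  structure(list(fluid = fl, projectile = proj, channel = ch,
                 grid_targets = list(dz = grid$dz,
                                     total_time = grid$total_time,
                                     dt = grid$dt,
                                     courant = grid$courant %||% 1),
                 outlet = outlet, friction = friction, celerity = celerity,
                 monitors = monitors, mean_free_path = mean_free_path,
                 name = name),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from a YAML file
#'
#' @param path path to a YAML config file; see the packaged presets under
#'   \code{system.file("extdata", package = "cellhammer")} for the schema.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(fluid = cfg$fluid %||% "water",
             projectile = cfg$projectile, channel = cfg$channel,
             grid = cfg$grid,
             outlet = cfg$outlet %||% "constant_pressure",
             friction = cfg$friction %||% "quasi_steady",
             celerity = cfg$celerity %||% "thorley",
             monitors = unlist(cfg$monitors %||% c(0.25, 0.5, 0.75)),
             mean_free_path = cfg$mean_free_path %||% 3e-10,
             name = cfg$name %||% tools::file_path_sans_ext(basename(path)))
}

#' Packaged case presets
#'
#' \code{"representative"}: the water-filled 3 x 3 x 60 mm rectangular
#' channel with a 0.01 m PMMA projectile at 3 m/s (a ~3 MPa inlet pulse),
#' stiff glass wall, constant-pressure outlet.
#' \code{"shot62"}: the classical water-hammer validation shot -- a 0.67 kg
#' steel projectile at 18.5 m/s into a water-filled 38.1 mm bore specimen
#' tube with 12.74 mm walls and a closed end; the tube material is not part
#' of the published record, so the preset assumes a near-rigid wall
#' (celerity correction off).
#'
#' @param name \code{"representative"} or \code{"shot62"}.
#' @return A [run_config()].
#' @export
preset_config <- function(name = c("representative", "shot62")) {
  name <- match.arg(name)
  read_run_config(system.file("extdata", paste0(name, ".yaml"),
                              package = "cellhammer", mustWork = TRUE))
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config '%s'\n", x$name))
  print(x$fluid); print(x$projectile); print(x$channel)
  cat(sprintf("  outlet = %s, friction = %s, celerity = %s\n",
              x$outlet, x$friction, x$celerity))
  invisible(x)
}

# -- design / simulation / validation runs ----------------------------------

#' Design pass: source pulse, acoustics and grid, with criteria flags
#'
#' Executes the impact-source and channel-acoustics computations and the
#' Courant grid design, without the PDE solve, and flags any violated design
#' criterion (continuum, rigidity, Courant).
#'
#' @param config a [run_config()].
#' @return An object of class \code{"design_report"}: the [impact_pulse()],
#'   [acoustics_report()], [design_grid()] results, a logical \code{criteria}
#'   vector (\code{continuum_ok}, \code{rigid_ok}, \code{courant_ok}) and the
#'   echoed config.
#' @export
run_design <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pulse <- impact_pulse(config$fluid, config$projectile)
  ac <- acoustics_report(config$fluid, config$channel,
                         mean_free_path = config$mean_free_path,
                         rigid = config$celerity == "rigid")
  gt <- config$grid_targets
  grid <- design_grid(cf = ac$cf, l = config$channel$l,
                      total_time = gt$total_time, dz = gt$dz,
                      dt = gt$dt, courant = gt$courant)
  crit <- c(continuum_ok = ac$continuum_ok, rigid_ok = ac$rigid_ok,
            courant_ok = grid$courant <= 1 + 1e-9)
  structure(list(pulse = pulse, acoustics = ac, grid = grid,
                 criteria = crit, config = config),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("Design report '%s'\n", x$config$name))
  print(x$pulse); print(x$acoustics); print(x$grid)
  ok <- all(x$criteria)
  cat(sprintf("  criteria: %s\n", paste(sprintf("%s=%s", names(x$criteria),
                                                x$criteria), collapse = ", ")))
  cat(if (ok) "  all design criteria satisfied\n"
      else "  WARNING: some design criteria violated\n")
  invisible(x)
}

#' Full simulation run
#'
#' [run_design()] followed by the 1D transient solve and monitor-point
#' stress extraction at the configured positions.
#'
#' @param config a [run_config()].
#' @param force run even if a design criterion is violated.
#' @return List with \code{design} (a \code{"design_report"}), \code{field}
#'   (a \code{"wave_field"}), \code{traces} (monitor traces with shear), and
#'   \code{summary}: peak pressure/velocity and attenuation per 15 mm.
#' @export
run_simulation <- function(config, force = FALSE) {
  des <- run_design(config)
  if (!all(des$criteria) && !force)
    stop("design criteria violated (",
         paste(names(des$criteria)[!des$criteria], collapse = ", "),
         "); use force = TRUE to run anyway")
  field <- solve_transient(config$fluid, config$channel, des$pulse, des$grid,
                           outlet = config$outlet,
                           friction = config$friction)
  traces <- monitor(field, config$monitors)
  att <- tryCatch(peak_attenuation(field, 0.015), error = function(e) NA_real_)
  list(design = des, field = field, traces = traces,
       summary = list(peak_pressure = max(field$p),
                      peak_velocity = max(abs(field$u)),
                      peak_tau_z = max(vapply(traces, function(tr)
                        max(tr$tau_z), numeric(1L))),
                      attenuation_per_15mm = att))
}

#' Validation against the classical projectile water-hammer shot
#'
#' Computes the impedance-matched peak pressure predicted by the source
#' model for the configured projectile/fluid pair and compares it with the
#' recorded reference peaks of the classical validation shot (numerical
#' 25.03 MPa, experimental 27.20 MPa at the impacted end).
#'
#' @param config a [run_config()]; defaults to the shot62 preset.
#' @return An object of class \code{"validation_report"}: predicted gauge
#'   and absolute peaks (Pa), the Joukowsky rigid-projectile bound, the
#'   reference values and relative errors.
#' @export
run_validation_shot62 <- function(config = preset_config("shot62")) {
  stopifnot(inherits(config, "run_config"))
  pk <- matched_amplitude(config$fluid, config$projectile)
  jk <- impedance(config$fluid) * config$projectile$velocity
  ref <- c(numerical = 25.03e6, experimental = 27.20e6)
  structure(list(peak_gauge = pk,
                 peak_total = pk + config$fluid$p0,
                 joukowsky_bound = jk,
                 reference = ref,
                 rel_error = pk / ref - 1,
                 config = config),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Projectile water-hammer validation\n")
  cat(sprintf("  predicted peak: %.2f MPa gauge (%.2f MPa absolute)\n",
              x$peak_gauge / 1e6, x$peak_total / 1e6))
  cat(sprintf("  Joukowsky rigid-projectile bound: %.2f MPa\n",
              x$joukowsky_bound / 1e6))
  for (nm in names(x$reference))
    cat(sprintf("  vs %s %.2f MPa: %+.1f%%\n", nm, x$reference[[nm]] / 1e6,
                100 * x$rel_error[[nm]]))
  invisible(x)
}

# -- serialization ----------------------------------------------------------

config_echo <- function(config) {
  list(name = config$name,
       fluid = unclass(config$fluid)[c("rho0", "c0", "mu", "B", "gamma", "p0")],
       projectile = list(material = unclass(config$projectile$material),
                         length = config$projectile$length,
                         area = config$projectile$area,
                         mass = config$projectile$mass,
                         velocity = config$projectile$velocity),
       channel = list(a = config$channel$a, b = config$channel$b,
                      e = config$channel$e, l = config$channel$l,
                      wall = unclass(config$channel$wall)),
       grid = config$grid_targets, outlet = config$outlet,
       friction = config$friction, celerity = config$celerity,
       monitors = config$monitors, mean_free_path = config$mean_free_path)
}

#' Serialize a design report to JSON
#'
#' Writes the design report -- source pulse, acoustics, grid, criteria flags
#' and the full echoed configuration -- as JSON.
#'
#' @param report a [run_design()] result.
#' @param path output file; when \code{NULL} the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_design_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "design_report"))
  obj <- list(
    pulse = list(p_peak = report$pulse$p_peak, lambda = report$pulse$lam,
                 ambient = report$pulse$ambient),
    acoustics = unclass(report$acoustics)[c("cf", "Kmod", "beta", "R", "Kn",
                                            "rigid_ok", "continuum_ok",
                                            "rigid_assumed")],
    grid = unclass(report$grid)[c("dz", "dt", "courant", "nz", "nt",
                                  "cf", "l", "total_time")],
    criteria = as.list(report$criteria),
    config = config_echo(report$config))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Export monitor traces as a long-format data.frame
#'
#' @param traces list of monitor traces from [monitor()].
#' @return data.frame with columns \code{z_m}, \code{frac_l}, \code{t_s},
#'   \code{p_Pa}, \code{tau_z_Pa}, \code{tau_x_Pa}, \code{delta_m}.
#' @export
traces_to_df <- function(traces) {
  do.call(rbind, lapply(traces, function(tr)
    data.frame(z_m = tr$position, frac_l = tr$frac, t_s = tr$t,
               p_Pa = tr$p, tau_z_Pa = tr$tau_z, tau_x_Pa = 0,
               delta_m = tr$delta)))
}
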