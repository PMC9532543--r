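# Shared fixtures: built in code, kept small so the solver tests stay fast.

water <- water_spec()

pmma_projectile <- function(velocity = 3, length = 0.01, area = 9e-6)
  projectile_spec(material_preset("pmma"), length = length, area = area,
                  velocity = velocity)

culture_channel <- function(l = 0.06)
  channel_spec(a = 0.003, b = 0.003, e = 0.003, l = l,
               wall = material_preset("glass"))

# small representative solve reused by several tests (memoised)
small_solve <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ch <- culture_channel(l = 0.03)
      pulse <- impact_pulse(water, pmma_projectile())
      cf <- celerity_rect(water, ch)
      grid <- design_grid(cf, l = ch$l, total_time = 2.5 * ch$l / cf,
                          dz = 2e-4, courant = 1)
      cache <<- solve_transient(water, ch, pulse, grid,
                                outlet = "constant_pressure",
                                friction = "quasi_steady")
    }
    cache
  }
})
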