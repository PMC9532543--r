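# Representative case: water-filled 3 x 3 x 60 mm rectangular culture
# channel, 0.01 m PMMA projectile. The 3 m/s impact velocity produces the
# ~3 MPa inlet pulse used throughout the worked examples.
name: representative
fluid: water
projectile:
  material: pmma
  length: 0.01        # m
  velocity: 3.0       # m/s
  # area defaults to the channel bore (a*b)
channel:
  a: 0.003            # m, long side
  b: 0.003            # m, short side
  e: 0.003            # m, wall thickness
  l: 0.06             # m, length
  wall: glass         # stiff wall; compliance correction still applied
  delta_cell: 1.0e-5  # m, average cell height (report-only)
  cell_density: sparse
grid:
  dz: 1.0e-4          # m
  total_time: 4.2e-5  # s (one full traversal)
  courant: 1.0        # dt derived as courant * dz / cf
outlet: constant_pressure
friction: quasi_steady
celerity: thorley
monitors: [0.25, 0.5, 0.75]
mean_free_path: 3.0e-10   # m, liquid water molecular scale
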