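# Classical projectile water-hammer validation shot: 0.67 kg steel
# projectile at 18.5 m/s into a water-filled specimen tube, 38.1 mm bore,
# 12.74 mm wall, closed far end. The tube material is not part of the
# published record, so the wall is taken near-rigid (celerity correction
# off) and the bore is represented by an equal-area square section; the
# tube length is likewise unrecorded and the 0.2 m used here only serves
# to exhibit the reflected wave.
name: shot62
fluid: water
projectile:
  material: steel
  length: 0.05          # m, nominal (mass given explicitly)
  mass: 0.67            # kg
  velocity: 18.5        # m/s
  area: 1.14009e-3      # m^2, bore area pi*(0.0381/2)^2
channel:
  a: 0.033765           # m, equal-area square equivalent of the 38.1 mm bore
  b: 0.033765
  e: 0.01274            # m, wall thickness
  l: 0.2                # m (assumed; see header note)
  wall: steel
  cell_density: none
grid:
  dz: 1.0e-3            # m
  total_time: 4.2e-4    # s, covers the closed-end reflection
  courant: 1.0
outlet: closed
friction: quasi_steady
celerity: rigid         # near-rigid wall assumption, cf = c0
monitors: [0.05, 0.5]
mean_free_path: 3.0e-10
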