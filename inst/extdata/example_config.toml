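# Example configuration: stress-relaxation run on a small slab.
# Any key left out falls back to the documented default.

[sim]
d = 2
dx = 0.002          # grid spacing (m)
dt = 0.0001         # time step (s)
nn = [96, 16]       # grid nodes per axis
bc_margin = 2

[material]
E = 10000           # Young's modulus (Pa); converted to mu0/lambda0
nu = 0.4
xi = 10             # plastic hardening coefficient
theta_c = 0.05      # compression limit ratio
theta_s = 0.10      # extension limit ratio
k_c = 0.05          # per-frame viscosity constants
k_s = 0.05
plasticity_mode = "stateful"

[specimen]
extents = [0.06, 0.01]   # slab size (m)
particles_per_cell = 4
jitter = 0.0
density = 1040           # kg/m^3

[experiment]
kind = "relax"
target_strain = 0.11
hold_duration = 0.05
pull_rate = 0.1
record_every = 20
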