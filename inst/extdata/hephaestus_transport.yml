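# Transport-model parameter blocks for the Mediterranean Ridge brine lakes.
# Ds: effective sediment diffusion coefficient, m^2/s
# Vs: average linear pore-water velocity, m/s (positive downward)
# C0: brine boundary value at z = 0; Cbg: deep background value
# t:  emplacement timing used for the forward curves, s
hephaestus_mg:
  Ds: 2.4e-10
  Vs: 9.51e-11
  C0: 4720
  Cbg: 61
  t: 2.2e+10
hephaestus_cl:
  Ds: 2.4e-10
  Vs: 9.51e-11
  C0: 9120
  Cbg: 630
  t: 2.2e+10
hephaestus_dD:
  Ds: 2.96e-10
  Vs: 9.51e-11
  C0: -16.5
  Cbg: 5.1
  t: 2.2e+10
discovery_cl:
  Ds: 2.4e-10
  Vs: 9.51e-11
  C0: 10150
  Cbg: 630
  t: 6.31e+10
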