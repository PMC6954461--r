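# Gallium-68 physical decay data (standard nuclear decay tables;
# ENSDF/ICRP-107-style values, rounded).
#   half_life_min : physical half-life, minutes
#   delta_np_mev  : mean non-penetrating (beta+ / conversion-electron / Auger)
#                   energy emitted per decay, MeV
#   photons       : penetrating emissions, energy (MeV) and yield per decay;
#                   0.511 MeV annihilation yield = 2 x beta+ branching (0.889)
name: Ga-68
half_life_min: 67.71
delta_np_mev: 0.740
photons:
  - energy_mev: 0.511
    yield: 1.778
  - energy_mev: 1.077
    yield: 0.032
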