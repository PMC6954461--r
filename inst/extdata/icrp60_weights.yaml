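# ICRP Publication 60 tissue weighting factors (sum = 1).
# tissue_map resolves weighting-scheme tissue names to reference-phantom
# organ ids where they differ (standard surrogates: the thymus dose stands
# in for the oesophagus, the lower-large-intestine wall for the colon,
# osteogenic cells for the bone surface).  gonads is resolved to testes or
# ovaries by sex at evaluation time.
# remainder: mass-weighted mean absorbed dose over the listed tissues.
scheme: icrp60
weights:
  gonads: 0.20
  red_marrow: 0.12
  colon: 0.12
  lungs: 0.12
  stomach_wall: 0.12
  urinary_bladder_wall: 0.05
  breasts: 0.05
  liver: 0.05
  oesophagus: 0.05
  thyroid: 0.05
  skin: 0.01
  bone_surface: 0.01
  remainder: 0.05
tissue_map:
  colon: lower_large_intestine_wall
  oesophagus: thymus
  bone_surface: osteogenic_cells
remainder_tissues:
  - adrenals
  - brain
  - kidneys
  - muscle
  - pancreas
  - small_intestine
  - spleen
  - thymus
  - upper_large_intestine_wall
  - uterus
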