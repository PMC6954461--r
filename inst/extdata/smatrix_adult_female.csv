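# Approximate synthetic S-value table (first-order model: local
# non-penetrating deposition + body-homogenized photons). Not a
# published dose-factor library.
target,source,s_mGy_per_MBq_h
adrenals,kidneys,0.00306434
brain,kidneys,0.00306434
breasts,kidneys,0.00306434
gallbladder_wall,kidneys,0.00306434
stomach_wall,kidneys,0.00306434
heart_wall,kidneys,0.00306434
kidneys,kidneys,1.55514
lower_large_intestine_wall,kidneys,0.00306434
upper_large_intestine_wall,kidneys,0.00306434
small_intestine,kidneys,0.00306434
liver,kidneys,0.00306434
lungs,kidneys,0.00306434
muscle,kidneys,0.00306434
ovaries,kidneys,0.00306434
pancreas,kidneys,0.00306434
red_marrow,kidneys,0.00306434
osteogenic_cells,kidneys,0.00306434
skin,kidneys,0.00306434
spleen,kidneys,0.00306434
thymus,kidneys,0.00306434
thyroid,kidneys,0.00306434
urinary_bladder_wall,kidneys,0.00306434
uterus,kidneys,0.00306434
total_body,kidneys,0.0105788
adrenals,pancreas,0.00306434
brain,pancreas,0.00306434
breasts,pancreas,0.00306434
gallbladder_wall,pancreas,0.00306434
stomach_wall,pancreas,0.00306434
heart_wall,pancreas,0.00306434
kidneys,pancreas,0.00306434
lower_large_intestine_wall,pancreas,0.00306434
upper_large_intestine_wall,pancreas,0.00306434
small_intestine,pancreas,0.00306434
liver,pancreas,0.00306434
lungs,pancreas,0.00306434
muscle,pancreas,0.00306434
ovaries,pancreas,0.00306434
pancreas,pancreas,5.02447
red_marrow,pancreas,0.00306434
osteogenic_cells,pancreas,0.00306434
skin,pancreas,0.00306434
spleen,pancreas,0.00306434
thymus,pancreas,0.00306434
thyroid,pancreas,0.00306434
urinary_bladder_wall,pancreas,0.00306434
uterus,pancreas,0.00306434
total_body,pancreas,0.0105788
adrenals,small_intestine,0.00306434
brain,small_intestine,0.00306434
breasts,small_intestine,0.00306434
gallbladder_wall,small_intestine,0.00306434
stomach_wall,small_intestine,0.00306434
heart_wall,small_intestine,0.00306434
kidneys,small_intestine,0.00306434
lower_large_intestine_wall,small_intestine,0.00306434
upper_large_intestine_wall,small_intestine,0.00306434
small_intestine,small_intestine,0.714431
liver,small_intestine,0.00306434
lungs,small_intestine,0.00306434
muscle,small_intestine,0.00306434
ovaries,small_intestine,0.00306434
pancreas,small_intestine,0.00306434
red_marrow,small_intestine,0.00306434
osteogenic_cells,small_intestine,0.00306434
skin,small_intestine,0.00306434
spleen,small_intestine,0.00306434
thymus,small_intestine,0.00306434
thyroid,small_intestine,0.00306434
urinary_bladder_wall,small_intestine,0.00306434
uterus,small_intestine,0.00306434
total_body,small_intestine,0.0105788
adrenals,total_body,0.0105788
brain,total_body,0.0105788
breasts,total_body,0.0105788
gallbladder_wall,total_body,0.0105788
stomach_wall,total_body,0.0105788
heart_wall,total_body,0.0105788
kidneys,total_body,0.0105788
lower_large_intestine_wall,total_body,0.0105788
upper_large_intestine_wall,total_body,0.0105788
small_intestine,total_body,0.0105788
liver,total_body,0.0105788
lungs,total_body,0.0105788
muscle,total_body,0.0105788
ovaries,total_body,0.0105788
pancreas,total_body,0.0105788
red_marrow,total_body,0.0105788
osteogenic_cells,total_body,0.0105788
skin,total_body,0.0105788
spleen,total_body,0.0105788
thymus,total_body,0.0105788
thyroid,total_body,0.0105788
urinary_bladder_wall,total_body,0.0105788
uterus,total_body,0.0105788
total_body,total_body,0.0105788
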