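# Approximate synthetic S-value table (first-order model: local
# non-penetrating deposition + body-homogenized photons). Not a
# published dose-factor library.
target,source,s_mGy_per_MBq_h
adrenals,kidneys,0.0111918
brain,kidneys,0.0111918
breasts,kidneys,0.0111918
gallbladder_wall,kidneys,0.0111918
stomach_wall,kidneys,0.0111918
heart_wall,kidneys,0.0111918
kidneys,kidneys,6.79688
lower_large_intestine_wall,kidneys,0.0111918
upper_large_intestine_wall,kidneys,0.0111918
small_intestine,kidneys,0.0111918
liver,kidneys,0.0111918
lungs,kidneys,0.0111918
muscle,kidneys,0.0111918
ovaries,kidneys,0.0111918
pancreas,kidneys,0.0111918
red_marrow,kidneys,0.0111918
osteogenic_cells,kidneys,0.0111918
skin,kidneys,0.0111918
spleen,kidneys,0.0111918
testes,kidneys,0.0111918
thymus,kidneys,0.0111918
thyroid,kidneys,0.0111918
urinary_bladder_wall,kidneys,0.0111918
uterus,kidneys,0.0111918
total_body,kidneys,0.0551033
adrenals,pancreas,0.0111918
brain,pancreas,0.0111918
breasts,pancreas,0.0111918
gallbladder_wall,pancreas,0.0111918
stomach_wall,pancreas,0.0111918
heart_wall,pancreas,0.0111918
kidneys,pancreas,0.0111918
lower_large_intestine_wall,pancreas,0.0111918
upper_large_intestine_wall,pancreas,0.0111918
small_intestine,pancreas,0.0111918
liver,pancreas,0.0111918
lungs,pancreas,0.0111918
muscle,pancreas,0.0111918
ovaries,pancreas,0.0111918
pancreas,pancreas,41.45
red_marrow,pancreas,0.0111918
osteogenic_cells,pancreas,0.0111918
skin,pancreas,0.0111918
spleen,pancreas,0.0111918
testes,pancreas,0.0111918
thymus,pancreas,0.0111918
thyroid,pancreas,0.0111918
urinary_bladder_wall,pancreas,0.0111918
uterus,pancreas,0.0111918
total_body,pancreas,0.0551033
adrenals,small_intestine,0.0111918
brain,small_intestine,0.0111918
breasts,small_intestine,0.0111918
gallbladder_wall,small_intestine,0.0111918
stomach_wall,small_intestine,0.0111918
heart_wall,small_intestine,0.0111918
kidneys,small_intestine,0.0111918
lower_large_intestine_wall,small_intestine,0.0111918
upper_large_intestine_wall,small_intestine,0.0111918
small_intestine,small_intestine,4.79081
liver,small_intestine,0.0111918
lungs,small_intestine,0.0111918
muscle,small_intestine,0.0111918
ovaries,small_intestine,0.0111918
pancreas,small_intestine,0.0111918
red_marrow,small_intestine,0.0111918
osteogenic_cells,small_intestine,0.0111918
skin,small_intestine,0.0111918
spleen,small_intestine,0.0111918
testes,small_intestine,0.0111918
thymus,small_intestine,0.0111918
thyroid,small_intestine,0.0111918
urinary_bladder_wall,small_intestine,0.0111918
uterus,small_intestine,0.0111918
total_body,small_intestine,0.0551033
adrenals,total_body,0.0551033
brain,total_body,0.0551033
breasts,total_body,0.0551033
gallbladder_wall,total_body,0.0551033
stomach_wall,total_body,0.0551033
heart_wall,total_body,0.0551033
kidneys,total_body,0.0551033
lower_large_intestine_wall,total_body,0.0551033
upper_large_intestine_wall,total_body,0.0551033
small_intestine,total_body,0.0551033
liver,total_body,0.0551033
lungs,total_body,0.0551033
muscle,total_body,0.0551033
ovaries,total_body,0.0551033
pancreas,total_body,0.0551033
red_marrow,total_body,0.0551033
osteogenic_cells,total_body,0.0551033
skin,total_body,0.0551033
spleen,total_body,0.0551033
testes,total_body,0.0551033
thymus,total_body,0.0551033
thyroid,total_body,0.0551033
urinary_bladder_wall,total_body,0.0551033
uterus,total_body,0.0551033
total_body,total_body,0.0551033
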