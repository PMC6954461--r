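# Approximate synthetic S-value table (first-order model: local
# non-penetrating deposition + body-homogenized photons). Not a
# published dose-factor library.
target,source,s_mGy_per_MBq_h
adrenals,kidneys,0.00250926
brain,kidneys,0.00250926
breasts,kidneys,0.00250926
gallbladder_wall,kidneys,0.00250926
stomach_wall,kidneys,0.00250926
heart_wall,kidneys,0.00250926
kidneys,kidneys,1.43
lower_large_intestine_wall,kidneys,0.00250926
upper_large_intestine_wall,kidneys,0.00250926
small_intestine,kidneys,0.00250926
liver,kidneys,0.00250926
lungs,kidneys,0.00250926
muscle,kidneys,0.00250926
pancreas,kidneys,0.00250926
red_marrow,kidneys,0.00250926
osteogenic_cells,kidneys,0.00250926
skin,kidneys,0.00250926
spleen,kidneys,0.00250926
testes,kidneys,0.00250926
thymus,kidneys,0.00250926
thyroid,kidneys,0.00250926
urinary_bladder_wall,kidneys,0.00250926
total_body,kidneys,0.00830058
adrenals,pancreas,0.00250926
brain,pancreas,0.00250926
breasts,pancreas,0.00250926
gallbladder_wall,pancreas,0.00250926
stomach_wall,pancreas,0.00250926
heart_wall,pancreas,0.00250926
kidneys,pancreas,0.00250926
lower_large_intestine_wall,pancreas,0.00250926
upper_large_intestine_wall,pancreas,0.00250926
small_intestine,pancreas,0.00250926
liver,pancreas,0.00250926
lungs,pancreas,0.00250926
muscle,pancreas,0.00250926
pancreas,pancreas,4.5287
red_marrow,pancreas,0.00250926
osteogenic_cells,pancreas,0.00250926
skin,pancreas,0.00250926
spleen,pancreas,0.00250926
testes,pancreas,0.00250926
thymus,pancreas,0.00250926
thyroid,pancreas,0.00250926
urinary_bladder_wall,pancreas,0.00250926
total_body,pancreas,0.00830058
adrenals,small_intestine,0.00250926
brain,small_intestine,0.00250926
breasts,small_intestine,0.00250926
gallbladder_wall,small_intestine,0.00250926
stomach_wall,small_intestine,0.00250926
heart_wall,small_intestine,0.00250926
kidneys,small_intestine,0.00250926
lower_large_intestine_wall,small_intestine,0.00250926
upper_large_intestine_wall,small_intestine,0.00250926
small_intestine,small_intestine,0.632967
liver,small_intestine,0.00250926
lungs,small_intestine,0.00250926
muscle,small_intestine,0.00250926
pancreas,small_intestine,0.00250926
red_marrow,small_intestine,0.00250926
osteogenic_cells,small_intestine,0.00250926
skin,small_intestine,0.00250926
spleen,small_intestine,0.00250926
testes,small_intestine,0.00250926
thymus,small_intestine,0.00250926
thyroid,small_intestine,0.00250926
urinary_bladder_wall,small_intestine,0.00250926
total_body,small_intestine,0.00830058
adrenals,total_body,0.00830058
brain,total_body,0.00830058
breasts,total_body,0.00830058
gallbladder_wall,total_body,0.00830058
stomach_wall,total_body,0.00830058
heart_wall,total_body,0.00830058
kidneys,total_body,0.00830058
lower_large_intestine_wall,total_body,0.00830058
upper_large_intestine_wall,total_body,0.00830058
small_intestine,total_body,0.00830058
liver,total_body,0.00830058
lungs,total_body,0.00830058
muscle,total_body,0.00830058
pancreas,total_body,0.00830058
red_marrow,total_body,0.00830058
osteogenic_cells,total_body,0.00830058
skin,total_body,0.00830058
spleen,total_body,0.00830058
testes,total_body,0.00830058
thymus,total_body,0.00830058
thyroid,total_body,0.00830058
urinary_bladder_wall,total_body,0.00830058
total_body,total_body,0.00830058
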