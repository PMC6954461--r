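# Approximate synthetic S-value table (first-order model: local
# non-penetrating deposition + body-homogenized photons). Not a
# published dose-factor library.
target,source,s_mGy_per_MBq_h
adrenals,kidneys,0.0226633
brain,kidneys,0.0226633
breasts,kidneys,0.0226633
gallbladder_wall,kidneys,0.0226633
stomach_wall,kidneys,0.0226633
heart_wall,kidneys,0.0226633
kidneys,kidneys,18.6611
lower_large_intestine_wall,kidneys,0.0226633
upper_large_intestine_wall,kidneys,0.0226633
small_intestine,kidneys,0.0226633
liver,kidneys,0.0226633
lungs,kidneys,0.0226633
muscle,kidneys,0.0226633
ovaries,kidneys,0.0226633
pancreas,kidneys,0.0226633
red_marrow,kidneys,0.0226633
osteogenic_cells,kidneys,0.0226633
skin,kidneys,0.0226633
spleen,kidneys,0.0226633
testes,kidneys,0.0226633
thymus,kidneys,0.0226633
thyroid,kidneys,0.0226633
urinary_bladder_wall,kidneys,0.0226633
uterus,kidneys,0.0226633
total_body,kidneys,0.141224
adrenals,pancreas,0.0226633
brain,pancreas,0.0226633
breasts,pancreas,0.0226633
gallbladder_wall,pancreas,0.0226633
stomach_wall,pancreas,0.0226633
heart_wall,pancreas,0.0226633
kidneys,pancreas,0.0226633
lower_large_intestine_wall,pancreas,0.0226633
upper_large_intestine_wall,pancreas,0.0226633
small_intestine,pancreas,0.0226633
liver,pancreas,0.0226633
lungs,pancreas,0.0226633
muscle,pancreas,0.0226633
ovaries,pancreas,0.0226633
pancreas,pancreas,152.458
red_marrow,pancreas,0.0226633
osteogenic_cells,pancreas,0.0226633
skin,pancreas,0.0226633
spleen,pancreas,0.0226633
testes,pancreas,0.0226633
thymus,pancreas,0.0226633
thyroid,pancreas,0.0226633
urinary_bladder_wall,pancreas,0.0226633
uterus,pancreas,0.0226633
total_body,pancreas,0.141224
adrenals,small_intestine,0.0226633
brain,small_intestine,0.0226633
breasts,small_intestine,0.0226633
gallbladder_wall,small_intestine,0.0226633
stomach_wall,small_intestine,0.0226633
heart_wall,small_intestine,0.0226633
kidneys,small_intestine,0.0226633
lower_large_intestine_wall,small_intestine,0.0226633
upper_large_intestine_wall,small_intestine,0.0226633
small_intestine,small_intestine,13.1153
liver,small_intestine,0.0226633
lungs,small_intestine,0.0226633
muscle,small_intestine,0.0226633
ovaries,small_intestine,0.0226633
pancreas,small_intestine,0.0226633
red_marrow,small_intestine,0.0226633
osteogenic_cells,small_intestine,0.0226633
skin,small_intestine,0.0226633
spleen,small_intestine,0.0226633
testes,small_intestine,0.0226633
thymus,small_intestine,0.0226633
thyroid,small_intestine,0.0226633
urinary_bladder_wall,small_intestine,0.0226633
uterus,small_intestine,0.0226633
total_body,small_intestine,0.141224
adrenals,total_body,0.141224
brain,total_body,0.141224
breasts,total_body,0.141224
gallbladder_wall,total_body,0.141224
stomach_wall,total_body,0.141224
heart_wall,total_body,0.141224
kidneys,total_body,0.141224
lower_large_intestine_wall,total_body,0.141224
upper_large_intestine_wall,total_body,0.141224
small_intestine,total_body,0.141224
liver,total_body,0.141224
lungs,total_body,0.141224
muscle,total_body,0.141224
ovaries,total_body,0.141224
pancreas,total_body,0.141224
red_marrow,total_body,0.141224
osteogenic_cells,total_body,0.141224
skin,total_body,0.141224
spleen,total_body,0.141224
testes,total_body,0.141224
thymus,total_body,0.141224
thyroid,total_body,0.141224
urinary_bladder_wall,total_body,0.141224
uterus,total_body,0.141224
total_body,total_body,0.141224
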