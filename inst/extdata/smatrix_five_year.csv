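# Approximate synthetic S-value table (first-order model: local
# non-penetrating deposition + body-homogenized photons). Not a
# published dose-factor library.
target,source,s_mGy_per_MBq_h
adrenals,kidneys,0.00715684
brain,kidneys,0.00715684
breasts,kidneys,0.00715684
gallbladder_wall,kidneys,0.00715684
stomach_wall,kidneys,0.00715684
heart_wall,kidneys,0.00715684
kidneys,kidneys,3.68664
lower_large_intestine_wall,kidneys,0.00715684
upper_large_intestine_wall,kidneys,0.00715684
small_intestine,kidneys,0.00715684
liver,kidneys,0.00715684
lungs,kidneys,0.00715684
muscle,kidneys,0.00715684
ovaries,kidneys,0.00715684
pancreas,kidneys,0.00715684
red_marrow,kidneys,0.00715684
osteogenic_cells,kidneys,0.00715684
skin,kidneys,0.00715684
spleen,kidneys,0.00715684
testes,kidneys,0.00715684
thymus,kidneys,0.00715684
thyroid,kidneys,0.00715684
urinary_bladder_wall,kidneys,0.00715684
uterus,kidneys,0.00715684
total_body,kidneys,0.029621
adrenals,pancreas,0.00715684
brain,pancreas,0.00715684
breasts,pancreas,0.00715684
gallbladder_wall,pancreas,0.00715684
stomach_wall,pancreas,0.00715684
heart_wall,pancreas,0.00715684
kidneys,pancreas,0.00715684
lower_large_intestine_wall,pancreas,0.00715684
upper_large_intestine_wall,pancreas,0.00715684
small_intestine,pancreas,0.00715684
liver,pancreas,0.00715684
lungs,pancreas,0.00715684
muscle,pancreas,0.00715684
ovaries,pancreas,0.00715684
pancreas,pancreas,18.0927
red_marrow,pancreas,0.00715684
osteogenic_cells,pancreas,0.00715684
skin,pancreas,0.00715684
spleen,pancreas,0.00715684
testes,pancreas,0.00715684
thymus,pancreas,0.00715684
thyroid,pancreas,0.00715684
urinary_bladder_wall,pancreas,0.00715684
uterus,pancreas,0.00715684
total_body,pancreas,0.029621
adrenals,small_intestine,0.00715684
brain,small_intestine,0.00715684
breasts,small_intestine,0.00715684
gallbladder_wall,small_intestine,0.00715684
stomach_wall,small_intestine,0.00715684
heart_wall,small_intestine,0.00715684
kidneys,small_intestine,0.00715684
lower_large_intestine_wall,small_intestine,0.00715684
upper_large_intestine_wall,small_intestine,0.00715684
small_intestine,small_intestine,2.53272
liver,small_intestine,0.00715684
lungs,small_intestine,0.00715684
muscle,small_intestine,0.00715684
ovaries,small_intestine,0.00715684
pancreas,small_intestine,0.00715684
red_marrow,small_intestine,0.00715684
osteogenic_cells,small_intestine,0.00715684
skin,small_intestine,0.00715684
spleen,small_intestine,0.00715684
testes,small_intestine,0.00715684
thymus,small_intestine,0.00715684
thyroid,small_intestine,0.00715684
urinary_bladder_wall,small_intestine,0.00715684
uterus,small_intestine,0.00715684
total_body,small_intestine,0.029621
adrenals,total_body,0.029621
brain,total_body,0.029621
breasts,total_body,0.029621
gallbladder_wall,total_body,0.029621
stomach_wall,total_body,0.029621
heart_wall,total_body,0.029621
kidneys,total_body,0.029621
lower_large_intestine_wall,total_body,0.029621
upper_large_intestine_wall,total_body,0.029621
small_intestine,total_body,0.029621
liver,total_body,0.029621
lungs,total_body,0.029621
muscle,total_body,0.029621
ovaries,total_body,0.029621
pancreas,total_body,0.029621
red_marrow,total_body,0.029621
osteogenic_cells,total_body,0.029621
skin,total_body,0.029621
spleen,total_body,0.029621
testes,total_body,0.029621
thymus,total_body,0.029621
thyroid,total_body,0.029621
urinary_bladder_wall,total_body,0.029621
uterus,total_body,0.029621
total_body,total_body,0.029621
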