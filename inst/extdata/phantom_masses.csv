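model_id,organ,mass_g
adult_male,adrenals,16.3
adult_male,brain,1420
adult_male,breasts,26
adult_male,gallbladder_wall,10.5
adult_male,stomach_wall,158
adult_male,heart_wall,316
adult_male,kidneys,299
adult_male,lower_large_intestine_wall,167
adult_male,upper_large_intestine_wall,220
adult_male,small_intestine,677
adult_male,liver,1910
adult_male,lungs,1000
adult_male,muscle,28000
adult_male,pancreas,94.3
adult_male,red_marrow,1120
adult_male,osteogenic_cells,120
adult_male,skin,3010
adult_male,spleen,183
adult_male,testes,39.1
adult_male,thymus,20.9
adult_male,thyroid,20.7
adult_male,urinary_bladder_wall,47.6
adult_male,total_body,73700
adult_female,adrenals,14.0
adult_female,brain,1200
adult_female,breasts,351
adult_female,gallbladder_wall,8.0
adult_female,stomach_wall,140
adult_female,heart_wall,240
adult_female,kidneys,275
adult_female,lower_large_intestine_wall,160
adult_female,upper_large_intestine_wall,200
adult_female,small_intestine,600
adult_female,liver,1400
adult_female,lungs,800
adult_female,muscle,17000
adult_female,ovaries,8.7
adult_female,pancreas,85.0
adult_female,red_marrow,1050
adult_female,osteogenic_cells,100
adult_female,skin,2300
adult_female,spleen,150
adult_female,thymus,20.0
adult_female,thyroid,17.0
adult_female,urinary_bladder_wall,35.9
adult_female,uterus,79.0
adult_female,total_body,56800
newborn,adrenals,5.8
newborn,brain,352
newborn,breasts,2.1
newborn,gallbladder_wall,0.5
newborn,stomach_wall,6.4
newborn,heart_wall,25.4
newborn,kidneys,22.9
newborn,lower_large_intestine_wall,7.0
newborn,upper_large_intestine_wall,10.5
newborn,small_intestine,32.6
newborn,liver,121
newborn,lungs,50.6
newborn,muscle,760
newborn,ovaries,0.33
newborn,pancreas,2.8
newborn,red_marrow,47
newborn,osteogenic_cells,18
newborn,skin,118
newborn,spleen,9.1
newborn,testes,0.84
newborn,thymus,11.3
newborn,thyroid,1.29
newborn,urinary_bladder_wall,2.9
newborn,uterus,3.8
newborn,total_body,3600
one_year,adrenals,3.5
one_year,brain,884
one_year,breasts,4.4
one_year,gallbladder_wall,1.4
one_year,stomach_wall,21.8
one_year,heart_wall,50.6
one_year,kidneys,62.9
one_year,lower_large_intestine_wall,20.2
one_year,upper_large_intestine_wall,28.8
one_year,small_intestine,89.3
one_year,liver,292
one_year,lungs,143
one_year,muscle,1890
one_year,ovaries,0.72
one_year,pancreas,10.3
one_year,red_marrow,150
one_year,osteogenic_cells,35
one_year,skin,271
one_year,spleen,25.5
one_year,testes,1.5
one_year,thymus,22.9
one_year,thyroid,1.78
one_year,urinary_bladder_wall,7.7
one_year,uterus,1.45
one_year,total_body,9720
five_year,adrenals,5.3
five_year,brain,1260
five_year,breasts,10.9
five_year,gallbladder_wall,2.6
five_year,stomach_wall,49.1
five_year,heart_wall,92.8
five_year,kidneys,116
five_year,lower_large_intestine_wall,36.6
five_year,upper_large_intestine_wall,55.2
five_year,small_intestine,169
five_year,liver,584
five_year,lungs,290
five_year,muscle,5000
five_year,ovaries,1.73
five_year,pancreas,23.6
five_year,red_marrow,320
five_year,osteogenic_cells,60
five_year,skin,538
five_year,spleen,48.3
five_year,testes,1.6
five_year,thymus,29.6
five_year,thyroid,3.45
five_year,urinary_bladder_wall,14.5
five_year,uterus,2.7
five_year,total_body,19000
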