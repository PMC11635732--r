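component,max_points,direction,unit,zero_standard,full_standard,energy_per_unit
total_fruits,5,adequacy,per1000kcal,0,0.8,NA
whole_fruits,5,adequacy,per1000kcal,0,0.4,NA
total_vegetables,5,adequacy,per1000kcal,0,1.1,NA
greens_beans,5,adequacy,per1000kcal,0,0.2,NA
whole_grains,10,adequacy,per1000kcal,0,1.5,NA
dairy,10,adequacy,per1000kcal,0,1.3,NA
total_protein,5,adequacy,per1000kcal,0,2.5,NA
seafood_plant_protein,5,adequacy,per1000kcal,0,0.8,NA
fatty_acids,10,adequacy,ratio,1.2,2.5,NA
refined_grains,10,moderation,per1000kcal,4.3,1.8,NA
sodium,10,moderation,per1000kcal,2.0,1.1,NA
added_sugars,10,moderation,pct_energy,26,6.5,16
sat_fat,10,moderation,pct_energy,16,8,9
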