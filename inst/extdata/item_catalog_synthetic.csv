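item_id,domain,label,median_opinion,weight,frequency
his_none,history,No relevant history,1,1,6
his_hip_surgery,history,Hip surgery,2,2,1
his_radical_prostatectomy,history,Radical prostatectomy,2,2,1
his_repeated_turbt,history,Repeated TURBT (>3),2,2,1
his_bladder_perforation,history,Prior bladder perforation,2,2,1
his_instillations,history,MMC or BCG instillations,2,2,1
his_uti,history,UTI,2,2,1
his_obesity,history,Obese BMI > 30,3,3,1
his_pelvic_radiation,history,Pelvic radiation,3,3,1
his_open_bladder_surgery,history,Any open bladder surgery,3,3,1
his_bleeding_disorder,history,Bleeding disorder or Coumadin or anti-aggregant,3,3,1
his_asa45,history,ASA class 4-5,4,4,1
acc_none,access,No relevant features,1,1,6
acc_large_bladder,access,Large bladder (>500 mL),2,2,1
acc_trabeculations,access,Irregular bladder wall or trabeculations,2,2,1
acc_urethral_stricture,access,Urethral stricture,3,3,1
acc_bladder_neck,access,High or narrow bladder neck,3,3,1
acc_large_median_lobe,access,Large median lobe,3,3,1
acc_large_prostate,access,Large prostate (60-90 mL),3,3,1
acc_small_bladder,access,Small bladder (100-250 mL),3,3,1
acc_prolapse,access,Female prolapse or cystocele,3,3,1
acc_no_lithotomy,access,Not amenable to lithotomy position,4,4,1
acc_very_small_bladder,access,Very small bladder (<100 mL),4,4,1
acc_very_large_prostate,access,Very large prostate (>90 mL),4,4,1
acc_bladder_hernia,access,Bladder hernia,4,4,1
acc_thin_bladder_wall,access,Thin bladder wall,4,4,1
num_1_3,number,1-3 tumours,1,1,6
num_4_10,number,4-10 tumours,3,3,1
num_gt10,number,>10 tumours,4,4,1
siz_lt3,size,<3 cm,1,1,6
siz_second_look,size,Recent TURBT (second-look),2,2,1
siz_3_5,size,3-5 cm,3,3,1
siz_cis_area,size,Large micropapillary area or suspicious for CIS (>5 cm2),3,3,1
siz_gt5,size,>5 cm,4,4,1
loc_trigon,location,Trigon,1,1.5,6
loc_prostatic_urethra,location,Prostatic urethra,2,3,1
loc_bladder_neck,location,Bladder neck,2,3,1
loc_lateral_wall,location,Lateral wall,2,3,1
loc_posterior_wall,location,Posterior wall,3,4.5,1
loc_anterior_wall,location,Anterior wall,3,4.5,1
loc_ureteric_orifice,location,Ureteric orifice,3,4.5,1
loc_dome,location,Dome,4,6,1
loc_obturator_jerk,location,Anticipate obturator jerk,4,6,1
loc_diverticulum,location,Diverticulum,4,6,1
str_papillary,tumour_structure,Papillary pedunculated,2,NA,2
str_sessile,tumour_structure,Sessile broad-based,3,NA,1
str_flat_cis,tumour_structure,Flat lesion suspicious for CIS,2,NA,1
str_solid,tumour_structure,Solid appearance,3,NA,1
str_mixed,tumour_structure,Mixed papillary and solid,2,NA,1
ana_normal,bladder_anatomy,Normal capacity and wall,2,NA,3
ana_trabeculated,bladder_anatomy,Moderate trabeculation,3,NA,1
ana_reduced_capacity,bladder_anatomy,Moderately reduced capacity,3,NA,1
ana_post_radiation,bladder_anatomy,Post-radiation changes,3,NA,1
ana_diverticula,bladder_anatomy,Multiple small diverticula,3,NA,1
ana_wall_thickening,bladder_anatomy,Diffuse wall thickening,3,NA,1
ana_scarred,bladder_anatomy,Scarring from prior resections,3,NA,1
ana_augmented,bladder_anatomy,Wide bladder neck after surgery,2,NA,1
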