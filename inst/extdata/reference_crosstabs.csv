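characteristic,category,low,medium,high,very high
gender,Male,135,527,283,102
gender,Female,89,353,311,134
education,Doctorate,17,120,66,25
education,Master,81,358,260,77
education,Undergraduate,116,370,250,121
education,Junior college,7,25,16,11
education,Others,3,7,2,2
income_band,<=5000,48,181,98,49
income_band,5001-10000,122,383,283,112
income_band,10001-15000,37,185,137,47
income_band,>15000,17,128,76,28
title,Senior,15,116,57,24
title,Associate senior,58,226,208,56
title,Intermediate,87,312,206,94
title,Junior,61,209,120,60
title,Others,3,17,3,2
tenure_band,1-5,78,283,168,67
tenure_band,6-10,58,217,179,49
tenure_band,11-15,38,149,101,47
tenure_band,16-20,23,81,64,38
tenure_band,>20,27,150,82,35
area,Eastern,64,358,243,70
area,Central,108,305,194,78
area,Western,52,217,157,88
hospital_level,Tertiary A,118,595,375,146
hospital_level,Tertiary B,28,83,91,13
hospital_level,Secondary,66,184,122,75
hospital_level,First-tier,12,18,6,2
department,Internal,66,260,188,71
department,Surgical,61,265,102,53
department,Obstetrics and gynecology,19,64,96,13
department,Pediatrics,21,72,58,12
department,Others,57,219,150,87
hours_per_week,<=40,28,89,35,28
hours_per_week,41-60,124,475,346,117
hours_per_week,>60,72,316,213,91
outpatient_hours,<=8,79,301,155,49
outpatient_hours,~16,51,210,127,52
outpatient_hours,~24,47,179,158,56
outpatient_hours,~40,34,110,84,40
outpatient_hours,>40,13,80,70,39
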