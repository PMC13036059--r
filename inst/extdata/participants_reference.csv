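id,sex,age,height_cm,mass_kg,bmi,body_fat_pct,lean_mass_kg,bsa_m2,pa_r,viat_kmh,vo2max
P1,m,25,178,76.3,24.1,15.1,60.8,1.94,10,16.5,65.9
P2,f,27,179,68.4,21.3,15.8,53.9,1.84,10,13.3,47.5
P3,m,27,178,67.6,21.3,11.6,56,1.83,8,12.2,48.8
P4,m,29,181,83.6,24.1,10.2,66.6,2.05,7,12.2,59.2
P5,f,22,167,57.1,20.5,20.3,42.5,1.63,9,12.5,50
P6,m,22,170,70.4,24.3,18.1,54,1.82,9,13.3,57.9
P7,f,23,160,60.5,23.6,21.3,44.5,1.64,10,10.7,45.9
P8,m,23,177,72.6,23.1,14.1,58.4,1.89,6,11.2,56.9
P9,f,26,166,58.9,21.4,25.3,41.1,1.65,7,9.9,41
P10,f,24,175,65.2,21.3,13.6,52.8,1.78,7,10.4,41.8
P11,f,24,177,72.2,22.8,18.1,54.7,1.88,9,12.5,49.2
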