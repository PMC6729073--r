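dmu,admin_na,admin_pct,medical_na,medical_pct,caregiver_na,caregiver_pct,paramedical_na,paramedical_pct,beds_na,beds_pct
2,7,87.50,8,80.00,3,18.75,21,95.45,0,0.00
5,0,4.34,20,81.79,4,13.49,12,43.36,0,0.00
12,25,81.20,19,81.84,66,75.99,18,51.60,73,27.90
13,2,47.29,3,37.37,7,36.74,0,0.00,0,0.00
22,5,45.71,13,74.37,14,37.97,5,57.14,0,0.00
23,1,10.12,12,67.88,7,15.79,0,0.00,0,0.00
25,5,62.83,2,38.06,13,44.92,4,70.75,0,0.00
29,7,87.45,8,80.51,3,21.11,21,94.98,15,4.90
Mean,6,53.31,10,67.73,14,33.10,10,51.66,11,4.10
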