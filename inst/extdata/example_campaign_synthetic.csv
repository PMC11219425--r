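well_id,temperature_C,duration_d,ciliate_N0_per_mL,ciliate_Nt_per_mL,prey_P0_per_mL,prey_Pt_per_mL,frac_cocci
T5_w01,5,1,31,49,2033761.9077505,2033761.9077505,0.5
T5_w02,5,1,37.3333333333333,35,202677.185091999,202677.185091999,0.5
T5_w03,5,1,23,25.3333333333333,489889.39111167,489889.39111167,0.5
T5_w04,5,1,23.6666666666667,32,3156326.39847003,3156326.39847003,0.5
T5_w05,5,1,38.3333333333333,64.3333333333333,4959199.20224905,4959199.20224905,0.5
T5_w06,5,1,41,30.6666666666667,173423.714377906,173423.714377906,0.5
T5_w07,5,1,35.6666666666667,33.3333333333333,167789.782533409,167789.782533409,0.5
T5_w08,5,1,29,27,281496.868040704,281496.868040704,0.5
T15_w01,15,1,33.3333333333333,25,129129.066598395,129129.066598395,0.5
T15_w02,15,1,23,19.3333333333333,808401.397457398,808401.397457398,0.5
T15_w03,15,1,42.6666666666667,22,276754.223212775,276754.223212775,0.5
T15_w04,15,1,34,81.3333333333333,6106204.30693212,6106204.30693212,0.5
T15_w05,15,1,41,28.6666666666667,554518.827111355,554518.827111355,0.5
T15_w06,15,1,35,72.3333333333333,5256410.15523264,5256410.15523264,0.5
T15_w07,15,1,24.6666666666667,55.3333333333333,7392794.79614651,7392794.79614651,0.5
T15_w08,15,1,31.3333333333333,18,115853.822533839,115853.822533839,0.5
T21_w01,21,1,39.6666666666667,39.3333333333333,2753815.55442253,2753815.55442253,0.5
T21_w02,21,1,25.3333333333333,41.6666666666667,9524427.81429868,9524427.81429868,0.5
T21_w03,21,1,15.6666666666667,12,193393.164153882,193393.164153882,0.5
T21_w04,21,1,27.6666666666667,19,147192.680900132,147192.680900132,0.5
T21_w05,21,1,27.6666666666667,23.6666666666667,1205524.85278844,1205524.85278844,0.5
T21_w06,21,1,31.3333333333333,46.3333333333333,8736146.23724455,8736146.23724455,0.5
T21_w07,21,1,25,11,137869.819542744,137869.819542744,0.5
T21_w08,21,1,24,24,453321.518499341,453321.518499341,0.5
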