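{
 "A1": 64.15110593,
 "r_w": 5,
 "L_w": 3.6,
 "L_w_min": 1.0,
 "d_W": 1,
 "r_c": 1,
 "D_w": 9.538153075,
 "d_wc": 2.881072212,
 "d_wn": 0.582249123,
 "r_ex": 3.180277265,
 "r_im": 3,
 "d_min": 0.9,
 "d_max": 1.1,
 "k_ww": 4.8,
 "n3": 2,
 "k_cw1": 1.93,
 "n1": 6,
 "k_cw2": 1.52,
 "n2": 6,
 "k_cw3": 4.97,
 "n6": 6,
 "C_p": 7,
 "k_wc1": 3.1,
 "n4": 4,
 "k_wc2": 1.55,
 "n5": 6,
 "D_c": 1,
 "d_c": 1.4,
 "inner_potency": 0.75,
 "clv3_outer_max_layer": 2,
 "earlm_dwc_factor": 0.25,
 "ck_prod_L": 1,
 "ck_D_L": 1,
 "ck_d_L": 1,
 "ck_prod_R": 1,
 "ck_d_R": 1,
 "ck_k_on": 1,
 "ck_k_off": 0.1,
 "ck_d_X": 1,
 "ck_deep_zmin": 1.5,
 "ck_s_wc": 0.3,
 "ck_k_wc": 0.44,
 "ck_s_ex": 0.3,
 "ck_k_ex": 0.44,
 "ck_n": 2,
 "ode_Wp": 90,
 "clv3_pos_threshold": 0.1,
 "wus_pos_threshold": 0.1,
 "clv3_on": true,
 "ck_on": true,
 "self_stab_on": true
}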