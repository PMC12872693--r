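case_id,tapvc_type,weight_kg,circumference_mm,length_mm,velocity_m_s,m_over_lc_printed,m_over_l_printed
Case A,supra-cardiac,4.06,28.6,11.33,2.021,0.01253,0.3583
Case A,supra-cardiac,4.06,28.6,12.53,1.814,0.01133,0.324
Case A,supra-cardiac,4.06,28.6,13.53,1.642,0.00982,0.291
Case A,supra-cardiac,4.06,28.6,15.36,1.496,0.00924,0.2643
Case A,supra-cardiac,4.06,28.6,16.56,1.377,0.00857,0.2452
Case A,supra-cardiac,4.06,28.6,17.6,1.288,0.00815,0.2307
Case B,supra-cardiac,3.28,18.5,11.93,2.472,0.01486,0.2749
Case B,supra-cardiac,3.28,18.5,12.82,2.31,0.01383,0.2559
Case B,supra-cardiac,3.28,18.5,14.45,2.022,0.01101,0.227
Case B,supra-cardiac,3.28,18.5,16.1,1.81,0.0101,0.2037
Case B,supra-cardiac,3.28,18.5,16.95,1.707,0.00967,0.1935
Case B,supra-cardiac,3.28,18.5,18.33,1.608,0.00967,0.1789
Case C,supra-cardiac,3.64,21.8,11.41,2.38,0.01461,0.319
Case C,supra-cardiac,3.64,21.8,12.15,2.229,0.01372,0.2996
Case C,supra-cardiac,3.64,21.8,12.93,2.074,0.01289,0.2815
Case C,supra-cardiac,3.64,21.8,13.75,1.93,0.01212,0.2647
Case C,supra-cardiac,3.64,21.8,14.64,1.794,0.01088,0.2491
Case C,supra-cardiac,3.64,21.8,15.48,1.66,0.01077,0.2351
Case D,supra-cardiac,3.68,24.2,12.45,1.997,0.01221,0.2956
Case D,supra-cardiac,3.68,24.2,13.4,1.797,0.01135,0.2746
Case D,supra-cardiac,3.68,24.2,14.45,1.636,0.01052,0.2547
Case D,supra-cardiac,3.68,24.2,15.6,1.495,0.00914,0.2359
Case D,supra-cardiac,3.68,24.2,16.82,1.404,0.00904,0.2189
Case D,supra-cardiac,3.68,24.2,17.79,1.317,0.00855,0.2069
Case E,supra-cardiac,1.95,14.9,4.89,4.361,0.02685,0.399
Case E,supra-cardiac,1.95,14.9,5.37,3.96,0.02445,0.3633
Case E,supra-cardiac,1.95,14.9,6.13,3.629,0.02241,0.3326
Case E,supra-cardiac,1.95,14.9,6.52,3.227,0.0204,0.2991
Case E,supra-cardiac,1.95,14.9,7.55,2.81,0.01739,0.2582
Case E,supra-cardiac,1.95,14.9,8.12,2.582,0.01617,0.2401
Case F,infra-cardiac,3.35,29.61,10.41,1.678,0.01087,0.3218
Case F,infra-cardiac,3.35,29.61,11.4,1.548,0.00992,0.2939
Case F,infra-cardiac,3.35,29.61,12.34,1.433,0.00917,0.2715
Case F,infra-cardiac,3.35,29.61,13.32,1.341,0.00849,0.2515
Case F,infra-cardiac,3.35,29.61,14.25,1.251,0.00794,0.2351
Case F,infra-cardiac,3.35,29.61,15.23,1.151,0.00743,0.22
Case G,infra-cardiac,3.8,30.83,9.41,1.971,0.0131,0.4038
Case G,infra-cardiac,3.8,30.83,10.48,1.766,0.01176,0.3626
Case G,infra-cardiac,3.8,30.83,11.64,1.594,0.01059,0.3265
Case G,infra-cardiac,3.8,30.83,12.64,1.46,0.00975,0.3006
Case G,infra-cardiac,3.8,30.83,13.35,1.375,0.00923,0.2846
Case G,infra-cardiac,3.8,30.83,14.63,1.277,0.00842,0.2597
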