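case_id,weight_kg,incision_length_mm,circumference_mm,tapvc_type,calculated_velocity_printed,echo_velocity_m_s,cfd_case
01,3.27,18,19.2,infra-cardiac,1.547,1.66,FALSE
02,3.5,20,25.7,infra-cardiac,1.113,1.27,FALSE
03,3.65,20,21.8,supra-cardiac,1.368,1.52,FALSE
04,4.8,20,28.1,supra-cardiac,1.396,1.6,FALSE
05,2.56,15,22.9,infra-cardiac,1.218,1.32,FALSE
06,2.58,15,21.9,supra-cardiac,1.26,1.25,FALSE
07,3.3,12,24.9,supra-cardiac,1.805,1.3,FALSE
08,3.8,20,19.2,supra-cardiac,1.618,1.4,FALSE
09,3.72,18,18.4,supra-cardiac,1.836,1.64,FALSE
10,2.9,16,16.6,supra-cardiac,1.785,1.23,FALSE
11,2.86,15,25.2,infra-cardiac,1.237,1.37,FALSE
12,3.05,18,23.7,supra-cardiac,1.169,1.3,FALSE
13,3.86,15,21.5,supra-cardiac,1.957,1.52,FALSE
14,4.06,16,28.6,supra-cardiac,1.45,1.53,TRUE
15,3.68,18,24.2,supra-cardiac,1.381,1.35,TRUE
16,3.28,15,18.5,supra-cardiac,1.932,1.88,TRUE
17,3.64,16,22.5,supra-cardiac,1.653,1.26,FALSE
18,3.35,15,29.6,infra-cardiac,1.233,1.21,TRUE
19,3.8,15,30.8,infra-cardiac,1.345,1.28,TRUE
20,4.26,18,27.6,supra-cardiac,1.402,1.25,FALSE
21,3.4,15,26.3,supra-cardiac,1.409,1.4,FALSE
22,3.26,15,24.6,supra-cardiac,1.444,1.33,FALSE
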