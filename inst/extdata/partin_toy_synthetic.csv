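clinical_stage,psa_low,psa_high,gs_category,p_oc,p_ece,p_svi,p_lni
T1c,0,6,<=6,90,8,1,1
T1c,6,10,<=6,84,13,2,1
T1c,10,Inf,<=6,76,19,4,1
T1c,0,6,3+4,78,17,4,1
T1c,6,10,3+4,70,23,5,2
T1c,10,Inf,3+4,60,29,8,3
T1c,0,6,4+3,68,24,6,2
T1c,6,10,4+3,58,30,9,3
T1c,10,Inf,4+3,47,35,13,5
T1c,0,6,8,58,29,9,4
T1c,6,10,8,47,34,13,6
T1c,10,Inf,8,36,38,18,8
T1c,0,6,9-10,47,33,14,6
T1c,6,10,9-10,36,37,18,9
T1c,10,Inf,9-10,26,39,23,12
T2a,0,6,<=6,85,12,2,1
T2a,6,10,<=6,77,18,4,1
T2a,10,Inf,<=6,67,25,6,2
T2a,0,6,3+4,70,23,5,2
T2a,6,10,3+4,60,29,8,3
T2a,10,Inf,3+4,49,34,12,5
T2a,0,6,4+3,59,29,9,3
T2a,6,10,4+3,48,34,13,5
T2a,10,Inf,4+3,37,38,17,8
T2a,0,6,8,48,33,13,6
T2a,6,10,8,37,38,17,8
T2a,10,Inf,8,27,40,22,11
T2a,0,6,9-10,37,36,18,9
T2a,6,10,9-10,27,39,22,12
T2a,10,Inf,9-10,18,40,27,15
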