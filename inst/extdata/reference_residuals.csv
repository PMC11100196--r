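"name","type","scenario","ref_scenario","target","lo","hi","year","tol","weight","achieved","residual","within_tol"
"baseline_2030","level","baseline",NA,42.3,NA,NA,2030,0.5,5,41.9918415126588,-0.308158487341217,TRUE
"gpsp_2030","level","gpsp",NA,57.8,NA,NA,2030,0.5,3,57.5711983886201,-0.228801611379851,TRUE
"gpsp_gain","diff","gpsp","baseline",15.4,NA,NA,2030,0.5,2,15.5793568759614,0.179356875961366,TRUE
"wdp_et_2030","level","wdp_et",NA,48,NA,NA,2030,1,1,48.5889449399572,0.588944939957159,TRUE
"wdp_jtp_2030","level","wdp_jtp",NA,48,NA,NA,2030,1,1,48.521791865521,0.521791865521024,TRUE
"wdp_ii_gain","diff","wdp_ii","baseline",10,NA,NA,2030,0.5,2,9.78984045468042,-0.210159545319577,TRUE
"hec_ii_2030","level","hec_ii",NA,52.5,NA,NA,2030,1,1,51.8301181444087,-0.669881855591292,TRUE
"mixed1_2030","level","mixed1",NA,54,NA,NA,2030,1.5,1,54.7826403278828,0.782640327882802,TRUE
"mixed2_2030","level","mixed2",NA,54,NA,NA,2030,1.5,1,54.8432170358988,0.843217035898832,TRUE
"mixed3_2030","level","mixed3",NA,54,NA,NA,2030,1.5,1,54.0067123097465,0.00671230974648296,TRUE
"mixed4_band","range","mixed4",NA,NA,58,68,2030,0.5,1,61.2022890958441,0,TRUE
"mixed5_band","range","mixed5",NA,NA,58,68,2030,0.5,1,61.0397216943191,0,TRUE
"mixed6_band","range","mixed6",NA,NA,58,68,2030,0.5,1,68.7433187822354,0.743318782235406,FALSE
"demand_gap","range","hec_ii","hcs_ii",NA,1,3,2030,0.5,2,0.668308486813963,-0.331691513186037,TRUE
"supply_gap_et","range","wdp_ii","wdp_et",NA,3,5,2030,0.5,1,3.19273702738204,0,TRUE
"supply_gap_jtp","range","wdp_ii","wdp_jtp",NA,3,5,2030,0.5,1,3.25989010181818,0,TRUE
"mixed7_gain","diff","mixed7","baseline",33.1,NA,NA,2030,0.5,3,33.0096749874766,-0.0903250125234436,TRUE
"idr_peak_2030","level","idr_0.5",NA,75.2,NA,NA,2030,0.5,4,75.0015165001353,-0.198483499864665,TRUE
"idr_asym_gain","diff","idr_0.7","idr_0.3",9,NA,NA,2030,0.5,2,8.9760907042461,-0.0239092957538958,TRUE
"idr_peak_margin","diff","idr_0.5","idr_0.7",2,NA,NA,2030,0.5,1,0.493855612153595,-1.5061443878464,FALSE
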