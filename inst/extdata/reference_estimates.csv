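parameter,group,value,se,rse_pct,cv_pct
Tlag,men,0.677,0.0021,0,0.2
Ka,men,0.233,0.0058,2,42
V,men,49,1.5,3,43
CL,men,231,10,4,55
Tlag,women,0.38,0.00013,0,0.2
Ka,women,0.149,0.0037,2,42
V,women,33.3,0.88,3,43
CL,women,92.9,4,4,55
omega_Tlag,shared,0.0003,0.0021,809,NA
omega_Ka,shared,0.176,0.012,7,NA
omega_V,shared,0.182,0.013,7,NA
omega_CL,shared,0.305,0.022,7,NA
prop_error,shared,0.0281,0.0007,2,NA
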