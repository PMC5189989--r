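enantiomer,sex,cv_CL,cv_V,cv_Ka
S,male,0.59,0.44,0.40
S,female,0.49,0.34,0.40
R,male,0.70,0.52,0.40
R,female,0.59,0.36,0.40
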