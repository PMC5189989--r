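enantiomer,sex,V,CL,Ka,Tlag
S,female,34.9,101,0.161,0.38
S,male,55.3,253,0.241,0.67
R,female,38.1,120,0.165,0.39
R,male,63.9,316,0.234,0.59
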