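"name","md","a_lo","b_lo","a_hi","b_hi","mass_min","mass_max"
"13C",1.0033548378,0.000120174758808136,0,0.00135196603659153,0,0,1500
"2x13C",2.0067096756,0,0,0.000906594833392116,0,0,1500
"2H",1.0062767281,0,0,4.31299599453937e-05,0,0,1500
"15N",0.9970348693,0,0,0.000391424786221848,0,0,1500
"18O",2.0042449924,0,0,0.000192655653237367,0,0,1500
"34S",1.9957958776,0,0,0.00209726023791978,0,0,1500
"37Cl",1.9970499,0,0,0.0137124754864987,0,0,1500
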