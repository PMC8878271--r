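"name","mass_multi","mass_add","charge","polarity","provenance"
"[M+H]+",1,1.00727645199093,1,"positive","computed: (H - - - 1*m_e) / 1"
"[M+NH4]+",1,18.0338255528909,1,"positive","computed: (NH4 - - - 1*m_e) / 1"
"[M+Na]+",1,22.9892207020909,1,"positive","computed: (Na - - - 1*m_e) / 1"
"[M+K]+",1,38.9631579064909,1,"positive","computed: (K - - - 1*m_e) / 1"
"[M+Li]+",1,7.01545485669093,1,"positive","computed: (Li - - - 1*m_e) / 1"
"[M+CH3OH+H]+",1,33.0334912016909,1,"positive","computed: (CH4OH - - - 1*m_e) / 1"
"[M+ACN+H]+",1,42.0338255528909,1,"positive","computed: (C2H3NH - - - 1*m_e) / 1"
"[M+2ACN+H]+",1,83.0603746537909,1,"positive","computed: (C4H6N2H - - - 1*m_e) / 1"
"[M+ACN+Na]+",1,64.0157698029909,1,"positive","computed: (C2H3NNa - - - 1*m_e) / 1"
"[M+IsoProp+H]+",1,61.0647913292909,1,"positive","computed: (C3H8OH - - - 1*m_e) / 1"
"[M+DMSO+H]+",1,79.0212124398909,1,"positive","computed: (C2H6OSH - - - 1*m_e) / 1"
"[M+2Na-H]+",1,44.9711649521909,1,"positive","computed: (Na2 - H - 1*m_e) / 1"
"[M+2K-H]+",1,76.9190393609909,1,"positive","computed: (K2 - H - 1*m_e) / 1"
"[M+H-H2O]+",1,-17.0032882339091,1,"positive","computed: (H - H2O - 1*m_e) / 1"
"[M+H-2H2O]+",1,-35.0138529198091,1,"positive","computed: (H - H4O2 - 1*m_e) / 1"
"[M]+",1,-0.00054857990907,1,"positive","computed: (- - - - 1*m_e) / 1"
"[M+2H]2+",0.5,1.00727645199093,2,"positive","computed: (H2 - - - 2*m_e) / 2"
"[M+H+Na]2+",0.5,11.9982485770409,2,"positive","computed: (HNa - - - 2*m_e) / 2"
"[M+H+K]2+",0.5,19.9852171792409,2,"positive","computed: (HK - - - 2*m_e) / 2"
"[M+H+NH4]2+",0.5,9.52055100244093,2,"positive","computed: (NH5 - - - 2*m_e) / 2"
"[M+2Na]2+",0.5,22.9892207020909,2,"positive","computed: (Na2 - - - 2*m_e) / 2"
"[M+ACN+2H]2+",0.5,21.5205510024409,2,"positive","computed: (C2H5N - - - 2*m_e) / 2"
"[M+2ACN+2H]2+",0.5,42.0338255528909,2,"positive","computed: (C4H8N2 - - - 2*m_e) / 2"
"[M+3H]3+",0.333333333333333,1.00727645199093,3,"positive","computed: (H3 - - - 3*m_e) / 3"
"[M+2H+Na]3+",0.333333333333333,8.33459120202426,3,"positive","computed: (H2Na - - - 3*m_e) / 3"
"[M+H+2Na]3+",0.333333333333333,15.6619059520576,3,"positive","computed: (HNa2 - - - 3*m_e) / 3"
"[M+3Na]3+",0.333333333333333,22.9892207020909,3,"positive","computed: (Na3 - - - 3*m_e) / 3"
"[2M+H]+",2,1.00727645199093,1,"positive","computed: (H - - - 1*m_e) / 1"
"[2M+NH4]+",2,18.0338255528909,1,"positive","computed: (NH4 - - - 1*m_e) / 1"
"[2M+Na]+",2,22.9892207020909,1,"positive","computed: (Na - - - 1*m_e) / 1"
"[2M+K]+",2,38.9631579064909,1,"positive","computed: (K - - - 1*m_e) / 1"
"[2M+ACN+H]+",2,42.0338255528909,1,"positive","computed: (C2H3NH - - - 1*m_e) / 1"
"[3M+H]+",3,1.00727645199093,1,"positive","computed: (H - - - 1*m_e) / 1"
"[M-H]-",1,-1.00727645199093,-1,"negative","computed: (- - H - -1*m_e) / 1"
"[M-H2O-H]-",1,-19.0178411378909,-1,"negative","computed: (- - H3O - -1*m_e) / 1"
"[M+Na-2H]-",1,20.9746677981091,-1,"negative","computed: (Na - H2 - -1*m_e) / 1"
"[M+K-2H]-",1,36.9486050025091,-1,"negative","computed: (K - H2 - -1*m_e) / 1"
"[M+Li-2H]-",1,5.00090195270907,-1,"negative","computed: (Li - H2 - -1*m_e) / 1"
"[M+Cl]-",1,34.9694012619091,-1,"negative","computed: (Cl - - - -1*m_e) / 1"
"[M+Br]-",1,78.9188861799091,-1,"negative","computed: (Br - - - -1*m_e) / 1"
"[M+F]-",1,18.9989517426091,-1,"negative","computed: (F - - - -1*m_e) / 1"
"[M+HCOO]-",1,44.9982028560091,-1,"negative","computed: (CHO2 - - - -1*m_e) / 1"
"[M+CH3COO]-",1,59.0138529198091,-1,"negative","computed: (C2H3O2 - - - -1*m_e) / 1"
"[M+TFA-H]-",1,112.985587312209,-1,"negative","computed: (C2F3O2 - - - -1*m_e) / 1"
"[M+HCO3]-",1,60.9931174781091,-1,"negative","computed: (CHO3 - - - -1*m_e) / 1"
"[M+NO3]-",1,61.9883664514091,-1,"negative","computed: (NO3 - - - -1*m_e) / 1"
"[M+H2PO4]-",1,96.9696191305091,-1,"negative","computed: (H2O4P - - - -1*m_e) / 1"
"[M+HSO4]-",1,96.9601032746091,-1,"negative","computed: (HO4S - - - -1*m_e) / 1"
"[M]-",1,0.00054857990907,-1,"negative","computed: (- - - - -1*m_e) / 1"
"[M-2H]2-",0.5,-1.00727645199093,-2,"negative","computed: (- - H2 - -2*m_e) / 2"
"[M-3H]3-",0.333333333333333,-1.00727645199093,-3,"negative","computed: (- - H3 - -3*m_e) / 3"
"[2M-H]-",2,-1.00727645199093,-1,"negative","computed: (- - H - -1*m_e) / 1"
"[2M-H2O-H]-",2,-19.0178411378909,-1,"negative","computed: (- - H3O - -1*m_e) / 1"
"[2M+HCOO]-",2,44.9982028560091,-1,"negative","computed: (CHO2 - - - -1*m_e) / 1"
"[2M+CH3COO]-",2,59.0138529198091,-1,"negative","computed: (C2H3O2 - - - -1*m_e) / 1"
"[2M+Na-2H]-",2,20.9746677981091,-1,"negative","computed: (Na - H2 - -1*m_e) / 1"
"[2M+Cl]-",2,34.9694012619091,-1,"negative","computed: (Cl - - - -1*m_e) / 1"
"[3M-H]-",3,-1.00727645199093,-1,"negative","computed: (- - H - -1*m_e) / 1"
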