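visit,condition,group,parameter,value
2006,preB,SAI,aric_Rp,0.592
2006,preB,H,aric_Rp,0.451
2006,preB,SAI,aric_Cp,0.053
2006,preB,H,aric_Cp,0.100
2006,preB,SAI,eric_Rp,0.824
2006,preB,H,eric_Rp,0.501
2006,preB,SAI,eric_Cp,0.045
2006,preB,H,eric_Cp,0.115
2008,preB,SAI,aric_Rp,0.470
2008,preB,H,aric_Rp,0.438
2008,preB,SAI,aric_Cp,0.056
2008,preB,H,aric_Cp,0.136
2008,preB,SAI,eric_Rp,0.601
2008,preB,H,eric_Rp,0.472
2008,preB,SAI,eric_Cp,0.056
2008,preB,H,eric_Cp,0.155
2008,postB,SAI,aric_Rp,0.359
2008,postB,H,aric_Rp,0.316
2008,postB,SAI,aric_Cp,0.067
2008,postB,H,aric_Cp,0.162
2008,postB,SAI,eric_Rp,0.472
2008,postB,H,eric_Rp,0.386
2008,postB,SAI,eric_Cp,0.076
2008,postB,H,eric_Cp,0.173
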