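visit,condition,group,parameter,value
2006,preB,SAI,r5,0.73
2006,preB,SAI,ax,2.51
2006,preB,SAI,eric_Cp,0.045
2006,preB,H,r5,0.52
2006,preB,H,ax,1.09
2006,preB,H,eric_Cp,0.115
2008,preB,SAI,r5,0.63
2008,preB,SAI,ax,2.00
2008,preB,SAI,eric_Cp,0.056
2008,preB,H,r5,0.43
2008,preB,H,ax,0.80
2008,preB,H,eric_Cp,0.155
2008,postB,SAI,r5,0.53
2008,postB,SAI,ax,1.34
2008,postB,SAI,eric_Cp,0.076
2008,postB,H,r5,0.38
2008,postB,H,ax,0.57
2008,postB,H,eric_Cp,0.173
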