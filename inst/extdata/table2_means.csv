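visit,condition,group,parameter,value
2006,preB,SAI,r5,0.73
2006,preB,SAI,fdr,0.31
2006,preB,SAI,ax,2.51
2006,preB,H,r5,0.52
2006,preB,H,fdr,0.15
2006,preB,H,ax,1.09
2008,preB,SAI,r5,0.63
2008,preB,SAI,fdr,0.27
2008,preB,SAI,ax,2.00
2008,preB,H,r5,0.43
2008,preB,H,fdr,0.13
2008,preB,H,ax,0.80
2008,postB,SAI,r5,0.53
2008,postB,SAI,fdr,0.20
2008,postB,SAI,ax,1.34
2008,postB,H,r5,0.38
2008,postB,H,fdr,0.08
2008,postB,H,ax,0.57
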