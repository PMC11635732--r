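approach,category,n,weighted_pct
crossclass,High,4285,48.3
crossclass,Marginal,3065,30.8
crossclass,Low,1815,13.6
crossclass,VeryLow,1072,7.3
afssm,High,7914,86.0
afssm,Marginal,947,6.0
afssm,Low,829,4.7
afssm,VeryLow,547,3.3
pfs,High,5092,52.7
pfs,Marginal,3134,31.4
pfs,Low,1403,11.4
pfs,VeryLow,608,4.4
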