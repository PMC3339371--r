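patient,clinical,min_edrs,min_edrs_area,infl_edrs_area_lo,infl_edrs_area_hi,min_elung,infl_elung_lo,infl_elung_hi
1,10,20,25,14,16,25,13,17
2,12,15,15,6,9,15,6,9
3,10,15,20,15,17,15,8,10
4,10,25,20,16,18,30,26,27
5,12,25,25,22,24,25,21,24
6,11,15,20,7.5,12,15,7.5,10
7,7.5,5,10,5,7.5,5,5,5
8,12,20,25,21,23,25,12,18
9,10,15,25,20,23,30,19,22
10,10,20,20,12,16,20,12,15
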