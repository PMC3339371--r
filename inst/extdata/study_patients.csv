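patient,sex,age,diagnosis,copd,pf_ratio,clinical_peep
1,F,61,Peritonitis + COPD,TRUE,214,10
2,M,22,Trauma,FALSE,180,12
3,M,55,Aspiration,FALSE,222,10
4,M,88,Pneumonia + COPD,TRUE,165,10
5,M,59,Pneumonia + COPD,TRUE,285,12
6,M,69,Trauma,FALSE,280,11
7,M,56,Legionnaires,FALSE,265,7.5
8,F,54,Aspiration,FALSE,302,12
9,M,37,H1N1 + COPD,TRUE,182,10
10,M,56,Legionnaires + COPD,TRUE,237,10
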