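rank,D9,D10,D11,D12
1,HR,HR,Glu,Glu
2,CRR,CRR,SBP,Weight
3,SpO2,SpO2,RR,SBP
4,RR,GCSM,MBP,MBP
5,GCST,Glu,HR,TEMP
6,TEMP,RR,PH,HR
7,GCSV,TEMP,Ht,GCSE
8,DBP,SBP,GCSE,SpO2
9,GCSE,MBP,GCST,CRR
10,Glu,DBP,TEMP,Ht
11,GCSM,GCST,DBP,DBP
12,PH,GCSE,GCSM,PH
13,Ht,PH,FiO2,GCST
14,SBP,GCSV,GCSV,RR
15,MBP,FiO2,Weight,GCSM
16,FiO2,Ht,SpO2,GCSV
17,Weight,Weight,CRR,FiO2
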