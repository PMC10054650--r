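treatment,concentration_ng_ml,n_exposed,n_dead,replicate,is_control
Cyt1Aa-demo,1000,11,7,R1,FALSE
Cyt1Aa-demo,1000,10,6,R2,FALSE
Cyt1Aa-demo,1000,11,8,R3,FALSE
Cyt1Aa-demo,500,11,7,R1,FALSE
Cyt1Aa-demo,500,14,7,R2,FALSE
Cyt1Aa-demo,500,15,12,R3,FALSE
Cyt1Aa-demo,250,13,9,R1,FALSE
Cyt1Aa-demo,250,15,10,R2,FALSE
Cyt1Aa-demo,250,10,5,R3,FALSE
Cyt1Aa-demo,125,10,4,R1,FALSE
Cyt1Aa-demo,125,14,5,R2,FALSE
Cyt1Aa-demo,125,12,7,R3,FALSE
Cyt1Aa-demo,62.5,10,2,R1,FALSE
Cyt1Aa-demo,62.5,15,4,R2,FALSE
Cyt1Aa-demo,62.5,13,4,R3,FALSE
Cyt1Aa-demo,31.25,10,1,R1,FALSE
Cyt1Aa-demo,31.25,11,3,R2,FALSE
Cyt1Aa-demo,31.25,11,2,R3,FALSE
Cyt1Aa-demo,0,14,0,R1,TRUE
Cyt1Aa-demo,0,10,0,R2,TRUE
Cyt1Aa-demo,0,15,0,R3,TRUE
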