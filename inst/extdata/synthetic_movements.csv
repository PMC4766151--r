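date,source,target,batch_size,type
2006-06-01,holding_A,holding_B,120,piglet
2006-06-01,holding_C,holding_D,85,fattening
2006-06-02,holding_A,holding_C,40,piglet
2006-06-04,holding_B,holding_D,60,fattening
2006-06-05,holding_A,holding_B,75,piglet
2006-06-07,holding_E,holding_A,30,sow
2006-06-08,holding_C,holding_D,90,fattening
2006-06-09,holding_A,holding_B,110,piglet
2006-06-10,holding_D,holding_E,25,sow
2006-06-12,holding_A,holding_D,55,fattening
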