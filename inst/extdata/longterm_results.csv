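name,arm,horizon,rate_percent,grade_typical
medical retreatment,Rezum,long,11.0,2
surgical retreatment,Rezum,long,4.4,4
medical retreatment,Urolift,long,10.7,2
surgical retreatment,Urolift,long,13.6,4
surgical implant removal,Urolift,long,9.3,4
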