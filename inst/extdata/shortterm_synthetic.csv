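name,arm,horizon,rate_percent,grade_typical,grade_min,grade_max
dysuria,Rezum,short,16.9,2,1,2
hematuria,Rezum,short,11.8,1,1,2
pain,Rezum,short,2.9,2,1,2
urinary urgency,Rezum,short,5.9,2,1,2
dysuria,Urolift,short,34.3,2,1,2
hematuria,Urolift,short,25.7,1,1,2
pain,Urolift,short,17.9,2,1,2
urinary urgency,Urolift,short,7.1,2,1,2
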