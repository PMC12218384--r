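sex,age_low,age_high,weekly_wage
female,16,24,420
female,25,34,540
female,35,44,580
female,45,54,560
female,55,64,530
female,65,100,480
male,16,24,450
male,25,34,600
male,35,44,700
male,45,54,720
male,55,64,680
male,65,100,550
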