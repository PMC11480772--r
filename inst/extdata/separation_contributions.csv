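water,salt_mM,term,value,stderr
TIP3P,81,sep_term,-20.0,1.4
TIP3P,177,sep_term,-15.4,2.2
TIP3P,450,sep_term,-9.9,1.3
TIP4P-D,81,sep_term,-7.2,5.2
TIP4P-D,177,sep_term,-6.0,2.0
TIP4P-D,450,sep_term,-4.0,1.1
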