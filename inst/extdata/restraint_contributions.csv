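water,salt_mM,term,value,stderr
TIP3P,81,minus_dG_p_S,-7.61,0.02
TIP3P,81,minus_dG_n_S,-3.81,0.01
TIP3P,81,minus_dG_o_S,-2.49,0.02
TIP3P,81,minus_dG_a_S,-0.85,0.01
TIP3P,81,sep_term,-28.3,0.2
TIP3P,81,dG_o_B,6.81,0
TIP3P,81,dG_p_B,13.1,0.1
TIP3P,81,dG_n_B,3.20,0.03
TIP3P,81,dG_b,-20.0,0.4
TIP3P,81,ddG_p,5.5,0.1
TIP3P,81,ddG_n,-0.62,0.03
TIP3P,81,ddG_o,4.32,0.01
TIP3P,177,minus_dG_p_S,-9.00,0.04
TIP3P,177,minus_dG_n_S,-1.84,0.02
TIP3P,177,minus_dG_o_S,-2.19,0.02
TIP3P,177,minus_dG_a_S,-0.34,0.01
TIP3P,177,sep_term,-26.0,0.3
TIP3P,177,dG_o_B,6.81,0
TIP3P,177,dG_p_B,12.7,0.2
TIP3P,177,dG_n_B,3.42,0.05
TIP3P,177,dG_b,-16.5,0.6
TIP3P,177,ddG_p,3.7,0.2
TIP3P,177,ddG_n,1.58,0.05
TIP3P,177,ddG_o,4.62,0.01
TIP3P,450,minus_dG_p_S,-8.73,0.05
TIP3P,450,minus_dG_n_S,-1.70,0.01
TIP3P,450,minus_dG_o_S,-1.38,0.01
TIP3P,450,minus_dG_a_S,-0.40,0.01
TIP3P,450,sep_term,-23.9,0.3
TIP3P,450,dG_o_B,6.81,0
TIP3P,450,dG_p_B,11.8,0.1
TIP3P,450,dG_n_B,2.05,0.04
TIP3P,450,dG_b,-15.5,0.5
TIP3P,450,ddG_p,3.1,0.1
TIP3P,450,ddG_n,0.35,0.04
TIP3P,450,ddG_o,5.43,0.01
TIP4P-D,81,minus_dG_p_S,-7.25,0.04
TIP4P-D,81,minus_dG_n_S,-2.25,0.05
TIP4P-D,81,minus_dG_o_S,-2.24,0.04
TIP4P-D,81,minus_dG_a_S,-0.93,0.01
TIP4P-D,81,sep_term,-24.6,0.3
TIP4P-D,81,dG_o_B,6.81,0
TIP4P-D,81,dG_p_B,14.1,0.2
TIP4P-D,81,dG_n_B,1.85,0.03
TIP4P-D,81,dG_b,-14.5,0.6
TIP4P-D,81,ddG_p,6.9,0.2
TIP4P-D,81,ddG_n,-0.4,0.1
TIP4P-D,81,ddG_o,4.57,0.01
TIP4P-D,177,minus_dG_p_S,-9.28,0.06
TIP4P-D,177,minus_dG_n_S,-2.10,0.03
TIP4P-D,177,minus_dG_o_S,-1.36,0.02
TIP4P-D,177,minus_dG_a_S,-0.44,0.01
TIP4P-D,177,sep_term,-21.7,0.3
TIP4P-D,177,dG_o_B,6.81,0
TIP4P-D,177,dG_p_B,16.4,0.2
TIP4P-D,177,dG_n_B,1.69,0.04
TIP4P-D,177,dG_b,-10.1,0.6
TIP4P-D,177,ddG_p,7.1,0.2
TIP4P-D,177,ddG_n,-0.4,0.1
TIP4P-D,177,ddG_o,5.45,0.01
TIP4P-D,450,minus_dG_p_S,-9.2,0.1
TIP4P-D,450,minus_dG_n_S,-1.87,0.03
TIP4P-D,450,minus_dG_o_S,-2.21,0.03
TIP4P-D,450,minus_dG_a_S,-0.44,0.01
TIP4P-D,450,sep_term,-17.5,0.3
TIP4P-D,450,dG_o_B,6.81,0
TIP4P-D,450,dG_p_B,15.7,0.2
TIP4P-D,450,dG_n_B,1.89,0.03
TIP4P-D,450,dG_b,-6.8,0.6
TIP4P-D,450,ddG_p,6.5,0.2
TIP4P-D,450,ddG_n,0.02,0.04
TIP4P-D,450,ddG_o,4.6,0.1
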