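leaf_id,treatment,day,A_N,g_sw,C_i,PPFD,T_leaf,F_s,F_m_prime,R_d
C_1,C,0,13.998882,0.2,288.00894,1800,30,1713.2616,2000,1.2
C_2,C,0,14.279604,0.2,285.76317,1800,30,1713.2616,2000,1.2
C_3,C,0,14.487957,0.2,284.09634,1800,30,1713.2616,2000,1.2
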