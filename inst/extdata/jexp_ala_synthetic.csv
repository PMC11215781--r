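observable,J_exp,s_exp
3J_HN_HA,5.91,0.1
3J_HN_Cp,1.39,0.11
3J_HA_Cp,1.82,0.12
3J_HN_CB,1.85,0.1
1J_N_CA,11.05,0.2
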