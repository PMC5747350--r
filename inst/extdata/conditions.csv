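"condition","class","end_time","untreated","AtorvaEx","T09Ex","GWEx","HC25","LPDS","siSREBF1","siSREBF2","siLDLR","siNPC1","siHMGCS1"
"untreated","drug48",100,TRUE,0,0,0,0,0,0,0,0,0,0
"atorva_low","drug48",100,FALSE,0.5,0,0,0,0,0,0,0,0,0
"atorva_high","drug48",100,FALSE,1,0,0,0,0,0,0,0,0,0
"t09_low","drug48",100,FALSE,0,0.5,0,0,0,0,0,0,0,0
"t09_high","drug48",100,FALSE,0,1,0,0,0,0,0,0,0,0
"gw_low","drug48",100,FALSE,0,0,0.5,0,0,0,0,0,0,0
"gw_high","drug48",100,FALSE,0,0,1,0,0,0,0,0,0,0
"hc25_low","drug48",100,FALSE,0,0,0,0.5,0,0,0,0,0,0
"hc25_high","drug48",100,FALSE,0,0,0,1,0,0,0,0,0,0
"lpds","drug48",100,FALSE,0,0,0,0,1,0,0,0,0,0
"lpds_atorva_low","drug48",100,FALSE,0.5,0,0,0,1,0,0,0,0,0
"lpds_atorva_high","drug48",100,FALSE,1,0,0,0,1,0,0,0,0,0
"si_srebf1_a","sirna72",150,FALSE,0,0,0,0,0,0.8,0,0,0,0
"si_srebf1_b","sirna72",150,FALSE,0,0,0,0,0,0.7,0,0,0,0
"si_srebf2_a","sirna72",150,FALSE,0,0,0,0,0,0,0.8,0,0,0
"si_srebf2_b","sirna72",150,FALSE,0,0,0,0,0,0,0.7,0,0,0
"si_ldlr_a","sirna72",150,FALSE,0,0,0,0,0,0,0,0.8,0,0
"si_ldlr_b","sirna72",150,FALSE,0,0,0,0,0,0,0,0.7,0,0
"si_npc1_a","sirna72",150,FALSE,0,0,0,0,0,0,0,0,0.8,0
"si_npc1_b","sirna72",150,FALSE,0,0,0,0,0,0,0,0,0.7,0
"si_hmgcs1_a","sirna72",150,FALSE,0,0,0,0,0,0,0,0,0,0.8
"si_hmgcs1_b","sirna72",150,FALSE,0,0,0,0,0,0,0,0,0,0.7
"si_srebf12","sirna72",150,FALSE,0,0,0,0,0,0.8,0.8,0,0,0
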