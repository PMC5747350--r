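"record","id","label","category","species","measured","initial_level","dynamic","source_param","source_scale","sources","target","mechanism","fixed","rate_param","km_param","ki_param","substrate","consumes","fixed_k","fixed_n"
"node","SREBP","SREBP","protein",,FALSE,0.5,TRUE,,1,,,,,,,,,,,
"node","SREBP1","SREBP1","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","SREBP2","SREBP2","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","LXR","LXR","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","HMGCR","HMGCR","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","HMGCS1","HMGCS1","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","ACAT2","ACAT2","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","LDLR","LDLR","protein",,FALSE,0.5,TRUE,,1,,,,,,,,,,,
"node","NPC1","NPC1","protein",,FALSE,0.5,TRUE,,1,,,,,,,,,,,
"node","INSIG1","INSIG1","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","SQLE","SQLE","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","LSS","LSS","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","IDI1","IDI1","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","MVD","MVD","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","DHCR7","DHCR7","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","DHCR24","DHCR24","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","FDFT1","FDFT1","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","MSMO1","MSMO1","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","FASN","FASN","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","ELOVL6","ELOVL6","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","ABCA1","ABCA1","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","ACAT2act","ACAT2act","activity",,FALSE,0.5,TRUE,,1,,,,,,,,,,,
"node","HMGCS1act","HMGCS1act","activity",,FALSE,0.5,TRUE,,1,,,,,,,,,,,
"node","AcetylCoA","AcetylCoA","metabolite_intracellular","AcetylCoA",TRUE,0.5,TRUE,"k1",0.5,,,,,,,,,,,
"node","AcetoacetylCoA","AcetoacetylCoA","metabolite_intracellular","AcetoacetylCoA",TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","HMGCoA","HMGCoA","metabolite_intracellular","HMGCoA",TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","Mevalonate","Mevalonate","metabolite_intracellular","Mevalonate",TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","CholER","CholER","metabolite_intracellular","Cholesterol",FALSE,0.5,TRUE,,1,,,,,,,,,,,
"node","CholMedia","CholMedia","metabolite_extracellular","Cholesterol",FALSE,0.5,TRUE,,1,,,,,,,,,,,
"node","AtorvaIn","AtorvaIn","drug_intracellular","Atorvastatin",TRUE,0,TRUE,,1,,,,,,,,,,,
"node","T09In","T09In","drug_intracellular","T0901317",TRUE,0,TRUE,,1,,,,,,,,,,,
"node","GWIn","GWIn","drug_intracellular","GW3965",TRUE,0,TRUE,,1,,,,,,,,,,,
"node","OHAtorva","OHAtorva","drug_intracellular","HydroxyAtorvastatin",FALSE,0,TRUE,,1,,,,,,,,,,,
"node","AtorvaLactone","AtorvaLactone","drug_intracellular","AtorvastatinLactone",FALSE,0,TRUE,,1,,,,,,,,,,,
"node","OHGW","OHGW","drug_intracellular","HydroxyGW3965",FALSE,0,TRUE,,1,,,,,,,,,,,
"node","AtorvaEx","AtorvaEx","drug_extracellular",,FALSE,0,FALSE,,1,,,,,,,,,,,
"node","T09Ex","T09Ex","drug_extracellular",,FALSE,0,FALSE,,1,,,,,,,,,,,
"node","GWEx","GWEx","drug_extracellular",,FALSE,0,FALSE,,1,,,,,,,,,,,
"node","HC25","HC25","drug_extracellular",,FALSE,0,FALSE,,1,,,,,,,,,,,
"node","LPDS","LPDS","stimulus",,FALSE,0,FALSE,,1,,,,,,,,,,,
"node","siSREBF1","siSREBF1","knockdown_input",,FALSE,0,FALSE,,1,,,,,,,,,,,
"node","siSREBF2","siSREBF2","knockdown_input",,FALSE,0,FALSE,,1,,,,,,,,,,,
"node","siLDLR","siLDLR","knockdown_input",,FALSE,0,FALSE,,1,,,,,,,,,,,
"node","siNPC1","siNPC1","knockdown_input",,FALSE,0,FALSE,,1,,,,,,,,,,,
"node","siHMGCS1","siHMGCS1","knockdown_input",,FALSE,0,FALSE,,1,,,,,,,,,,,
"edge","sterol_SREBP",,,,,,,,,"CholER:-1:1;SREBP1:-1:1;HC25:-1:1","SREBP","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP_SREBP1",,,,,,,,,"SREBP:1:1","SREBP1","hill_regulatory",TRUE,,,,,,0.5,2
"edge","SREBP_SREBP2",,,,,,,,,"SREBP:1:1","SREBP2","hill_regulatory",TRUE,,,,,,0.5,2
"edge","T09In_LXR",,,,,,,,,"T09In:1:1","LXR","hill_regulatory",FALSE,,,,,,0.5,2
"edge","GWIn_LXR",,,,,,,,,"GWIn:1:1","LXR","hill_regulatory",FALSE,,,,,,0.5,2
"edge","ACAT2_ACAT2act",,,,,,,,,"ACAT2:1:1","ACAT2act","hill_regulatory",FALSE,,,,,,0.5,2
"edge","HMGCS1_HMGCS1act",,,,,,,,,"HMGCS1:1:1","HMGCS1act","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_HMGCR",,,,,,,,,"SREBP2:1:1","HMGCR","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_HMGCS1",,,,,,,,,"SREBP2:1:1","HMGCS1","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_ACAT2",,,,,,,,,"SREBP2:1:1","ACAT2","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_LDLR",,,,,,,,,"SREBP2:1:1","LDLR","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_NPC1",,,,,,,,,"SREBP2:1:1","NPC1","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_INSIG1",,,,,,,,,"SREBP2:1:1","INSIG1","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_SQLE",,,,,,,,,"SREBP2:1:1","SQLE","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_LSS",,,,,,,,,"SREBP2:1:1","LSS","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_IDI1",,,,,,,,,"SREBP2:1:1","IDI1","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_MVD",,,,,,,,,"SREBP2:1:1","MVD","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_DHCR7",,,,,,,,,"SREBP2:1:1","DHCR7","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_DHCR24",,,,,,,,,"SREBP2:1:1","DHCR24","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_FDFT1",,,,,,,,,"SREBP2:1:1","FDFT1","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP2_MSMO1",,,,,,,,,"SREBP2:1:1","MSMO1","hill_regulatory",FALSE,,,,,,0.5,2
"edge","LXR_ABCA1",,,,,,,,,"LXR:1:1","ABCA1","hill_regulatory",FALSE,,,,,,0.5,2
"edge","LXR_SREBP1",,,,,,,,,"LXR:1:1","SREBP1","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP1_FASN",,,,,,,,,"SREBP1:1:1","FASN","hill_regulatory",FALSE,,,,,,0.5,2
"edge","SREBP1_ELOVL6",,,,,,,,,"SREBP1:1:1","ELOVL6","hill_regulatory",FALSE,,,,,,0.5,2
"edge","LPDS_CholMedia",,,,,,,,,"LPDS:-1:1","CholMedia","hill_regulatory",FALSE,,,,,,0.5,2
"edge","siSREBF1_SREBP1",,,,,,,,,"siSREBF1:-1:1","SREBP1","hill_regulatory",TRUE,,,,,,0.5,4
"edge","siSREBF2_SREBP2",,,,,,,,,"siSREBF2:-1:1","SREBP2","hill_regulatory",TRUE,,,,,,0.5,4
"edge","siLDLR_LDLR",,,,,,,,,"siLDLR:-1:1","LDLR","hill_regulatory",TRUE,,,,,,0.5,4
"edge","siNPC1_NPC1",,,,,,,,,"siNPC1:-1:1","NPC1","hill_regulatory",TRUE,,,,,,0.5,4
"edge","siHMGCS1_HMGCS1",,,,,,,,,"siHMGCS1:-1:1","HMGCS1","hill_regulatory",TRUE,,,,,,0.5,4
"edge","AtorvaEx_AtorvaIn",,,,,,,,,"AtorvaEx:1:1","AtorvaIn","hill_regulatory",FALSE,,,,,,0.5,2
"edge","T09Ex_T09In",,,,,,,,,"T09Ex:1:1","T09In","hill_regulatory",FALSE,,,,,,0.5,2
"edge","GWEx_GWIn",,,,,,,,,"GWEx:1:1","GWIn","hill_regulatory",FALSE,,,,,,0.5,2
"edge","AtorvaIn_OHAtorva",,,,,,,,,"AtorvaIn:1:1","OHAtorva","hill_regulatory",FALSE,,,,,,0.5,2
"edge","AtorvaIn_AtorvaLactone",,,,,,,,,"AtorvaIn:1:1","AtorvaLactone","hill_regulatory",FALSE,,,,,,0.5,2
"edge","GWIn_OHGW",,,,,,,,,"GWIn:1:1","OHGW","hill_regulatory",FALSE,,,,,,0.5,2
"edge","e_k2",,,,,,,,,"ACAT2act:1:1;AcetylCoA:1:2","AcetoacetylCoA","mass_action",FALSE,"k2",,,,"AcetylCoA",0.5,2
"edge","e_k3",,,,,,,,,"HMGCS1act:1:1;AcetylCoA:1:1;AcetoacetylCoA:1:1","HMGCoA","mass_action",FALSE,"k3",,,,"AcetylCoA;AcetoacetylCoA",0.5,2
"edge","e_k4",,,,,,,,,"HMGCR:1:1;HMGCoA:1:1;AtorvaIn:-1:1","Mevalonate","michaelis_menten_inhibited",FALSE,"k4","kM4","kI","HMGCoA","HMGCoA",0.5,2
"edge","e_k5",,,,,,,,,"Mevalonate:1:1","CholER","mass_action",FALSE,"k5",,,,"Mevalonate",0.5,2
"edge","e_k6",,,,,,,,,"CholMedia:1:1;LDLR:1:1;NPC1:1:1","CholER","uptake_product",FALSE,"k6",,,,,0.5,2
"edge","e_k7",,,,,,,,,"AcetylCoA:-1:1","AcetylCoA","mass_action",FALSE,"k7",,,,,0.5,2
"edge","e_k8",,,,,,,,,"CholER:-1:1","CholER","mass_action",FALSE,"k8",,,,,0.5,2
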