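"record","id","label","category","species","measured","initial_level","dynamic","source_param","source_scale","sources","target","mechanism","fixed","rate_param","km_param","ki_param","substrate","consumes","fixed_k","fixed_n"
"node","S","S","stimulus",,FALSE,0,FALSE,,1,,,,,,,,,,,
"node","D","D","drug_extracellular",,FALSE,0,FALSE,,1,,,,,,,,,,,
"node","TF","TF","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","P1","P1","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","P2","P2","protein",,TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","M1","M1","metabolite_intracellular","M1",TRUE,0.5,TRUE,"k1",1,,,,,,,,,,,
"node","M2","M2","metabolite_intracellular","M2",TRUE,0.5,TRUE,,1,,,,,,,,,,,
"node","M3","M3","metabolite_intracellular","M3",TRUE,0.5,TRUE,,1,,,,,,,,,,,
"edge","S_TF",,,,,,,,,"S:1:1","TF","hill_regulatory",FALSE,,,,,,0.5,2
"edge","TF_P1",,,,,,,,,"TF:1:1","P1","hill_regulatory",FALSE,,,,,,0.5,2
"edge","TF_P2",,,,,,,,,"TF:1:1","P2","hill_regulatory",FALSE,,,,,,0.5,2
"edge","e_m1drain",,,,,,,,,"M1:-1:1","M1","mass_action",FALSE,"k3",,,,,0.5,2
"edge","e_m2",,,,,,,,,"P1:1:1;M1:1:1","M2","mass_action",FALSE,"k2",,,,"M1",0.5,2
"edge","e_m3",,,,,,,,,"P2:1:1;M2:1:1;D:-1:1","M3","michaelis_menten_inhibited",FALSE,"k4","kM4","kI","M2","M2",0.5,2
"edge","e_m3drain",,,,,,,,,"M3:-1:1","M3","mass_action",FALSE,"k5",,,,,0.5,2
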