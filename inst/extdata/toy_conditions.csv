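"condition","class","end_time","untreated","S","D"
"untreated","drug48",40,TRUE,0.5,0
"stim_off","drug48",40,FALSE,0,0
"stim_high","drug48",40,FALSE,1,0
"inhibitor","drug48",40,FALSE,0.5,1
"stim_high_inhibitor","drug48",40,FALSE,1,1
"inhibitor_low","drug48",40,FALSE,0.5,0.5
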