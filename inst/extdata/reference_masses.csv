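"metabolite","monoisotopic_mass"
"T0901317",481.038975466
"GW3965",581.193606366
"hydroxy-GW3965",597.188822466
"hydroxy-atorvastatin",574.247367466
"atorvastatin lactone",540.241887466
"mevalonate",148.073559
"HMG-CoA",911.124494
"acetyl-CoA",809.125846
"cholesterol",386.354866
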