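variant,E_active_site,E_fragment,E_remainder,ddG_mean,ddG_sd
WT,-1000.00,-150.00,-846.85,-14.2,0.8
L210T,-980.00,-140.00,-839.35,-13.1,0.9
L210F,-1050.00,-180.00,-864.52,-16.8,1.1
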