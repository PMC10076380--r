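variant,E_active_site,E_fragment,E_remainder
WT,-2000.0,-500.0,-1455.0
L210T,-1990.0,-500.0,-1448.9
L210F,-2010.0,-500.0,-1459.2
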