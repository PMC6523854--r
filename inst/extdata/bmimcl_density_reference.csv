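T,rho_md_reported,rho_exp
298.15,1.169,1.082
323.15,1.157,1.067
348.15,1.138,1.053
363.15,1.130,1.045
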