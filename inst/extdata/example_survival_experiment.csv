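condition,drug,boron_ppm,fluence_n_per_cm2,surviving_fraction
beam_only,none,0,0,1
beam_only,none,0,5e10,0.9512
beam_only,none,0,1e11,0.9048
beam_only,none,0,1.5e11,0.8607
beam_only,none,0,2e11,0.8187
beam_plus_boron,BPA,25,0,1
beam_plus_boron,BPA,25,5e10,0.7426
beam_plus_boron,BPA,25,1e11,0.5514
beam_plus_boron,BPA,25,1.5e11,0.4095
beam_plus_boron,BPA,25,2e11,0.3041
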