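name,d0_bpa,d0_bsh,xnc,xcs
EL4,0.43,0.75,0.508,74.5
B16-BL6,0.91,1.25,0.3,202
SAS/neo,0.35,1.2,0.528,108
SAS/mp53,0.52,1.44,0.407,123
SCCVII,0.74,1.6,0.347,146
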