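name,d0_neutron_beam,d0_bpa_neutron,d0_bsh_neutron
EL4,0.98,0.52,0.81
B16-BL6,1.87,1.16,1.34
SAS/neo,2.42,0.41,1.27
SAS/mp53,2.51,0.6,1.57
SCCVII,2.25,1.36,2.55
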