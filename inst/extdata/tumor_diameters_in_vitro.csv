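name,nucleus_diameter_in_vivo_um,nucleus_diameter_in_vitro_um,cell_diameter_in_vivo_um,cell_diameter_in_vitro_um
EL4,9.8,9.7,12.3,12.5
B16-BL6,13.6,11.9,20.4,18.4
SAS/neo,12.1,11.6,14.9,14.9
SAS/mp53,11.8,12.8,15.9,16.2
SCCVII,13.0,13.6,18.5,16.8
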