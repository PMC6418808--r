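species_i	species_j	temperature_K	chi
PVA	PVA	298	0.00
PVA	H2O	298	0.23
PVA	PAM	298	0.15
PVA	SiO2	298	4.17
PAM	PAM	298	0.00
PAM	H2O	298	0.57
PAM	SiO2	298	2.48
H2O	SiO2	298	6.35
H2O	H2O	298	0.00
SiO2	SiO2	298	-0.44
PVA	PVA	328	0.00
PVA	H2O	328	0.20
PVA	PAM	328	0.14
PVA	SiO2	328	3.62
PAM	PAM	328	0.00
PAM	H2O	328	0.49
PAM	SiO2	328	2.25
H2O	SiO2	328	5.39
H2O	H2O	328	0.00
SiO2	SiO2	328	-0.52
PVA	PVA	358	0.00
PVA	H2O	358	0.18
PVA	PAM	358	0.12
PVA	SiO2	358	3.12
PAM	PAM	358	0.00
PAM	H2O	358	0.42
PAM	SiO2	358	2.01
H2O	SiO2	358	4.38
H2O	H2O	358	0.00
SiO2	SiO2	358	-0.61
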