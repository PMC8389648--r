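category	gene
cellular_cycle_signaling	EDN1
cellular_cycle_signaling	AKT1
cellular_cycle_signaling	IL1B
cellular_cycle_signaling	INS
membrane_transport	CDK5
membrane_transport	ATP1B1
metabolic_immunological	PTK2B
metabolic_immunological	MTOR
metabolic_immunological	APP
metabolic_immunological	KIT
metabolic_immunological	LEP
metabolic_immunological	MAPK3
metabolic_immunological	SRC
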