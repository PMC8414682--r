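TREG7	7-transcript T-cell/Treg-related diagnostic panel	DGKA	DLG1	ICOSLG	IKZF4	SMYD3	TCF3	TRIM28
TREG_CONSENSUS	Consensus Treg cell markers	FOXP3	CD4	IL2RA	ETS1	RUNX1
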