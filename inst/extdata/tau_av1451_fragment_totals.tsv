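site	system	delta_e_fibril	delta_e_solvent	delta_e_total
AD_site1	AD-tau	-35.3	-20.5	-55.8
CTE_site4	CTE-tau	-27.3	-22.1	-49.4
PiD_site3	PiD-tau	-53.1	-8.1	-61.2
AD_cryptic_C1	AD-tau cryptic	-80.5	-14.4	-94.9
AD_cryptic_C3	AD-tau cryptic	-41.1	-3.2	-44.3
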