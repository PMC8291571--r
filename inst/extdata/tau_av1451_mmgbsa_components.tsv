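site	system	e_vdw	e_elec	g_gb	g_sa	g_binding
AD_site1	AD-tau	-39.2	-11.8	24.1	-4.3	-31.2
AD_site2	AD-tau	-13.0	-0.3	6.2	-1.3	-8.4
AD_site3	AD-tau	-24.7	-15.1	24.1	-3.0	-18.6
AD_site4	AD-tau	-26.5	-24.6	35.3	-3.4	-19.3
CTE_site1	CTE-tau	-35.3	-7.9	24.7	-4.2	-22.7
CTE_site2	CTE-tau	-35.6	-20.9	36.3	-3.8	-24.0
CTE_site3	CTE-tau	-27.3	-24.2	34.5	-3.0	-20.1
CTE_site4	CTE-tau	-30.0	-14.0	22.6	-4.3	-25.8
CTE_site5	CTE-tau	-30.9	-6.8	17.5	-2.9	-23.1
PiD_site1	PiD-tau	-27.6	-9.5	21.3	-3.4	-19.2
PiD_site2	PiD-tau	-31.5	-12.7	25.9	-3.7	-21.9
PiD_site3	PiD-tau	-41.2	-19.0	28.9	-4.6	-35.9
PiD_site4	PiD-tau	-19.7	-7.2	16.6	-2.3	-12.5
AD_cryptic_C1	AD-tau cryptic	-37.6	-21.0	29.2	-4.1	-33.6
AD_cryptic_C3	AD-tau cryptic	-43.2	-19.4	26.2	-4.9	-41.3
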