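# Synthetic transcription of the PilV adhesin x recipient-strain
# transfer panel (heat-map style data reconstructed from the study's
# narrated results and receptor summary; not measured ground truth).
# BD = below the 1e-8 detection limit / not significant.
adhesin	BW25113	R1	R2	R3	R4	ClearColi	BW_dwaaL	BW_dwaaU	BW_dwaaR	BW_dwaaO	BW_dwaaB	BW_dwaaG	BW_dwaaQ	BW_dwaaY	BW_dwaaP	BW_dwaaF	BW_dwaaC	BW_dwaaE	BW_dgmhD	BW_pWaaK	BW_pWaaID	BW_pWaaX	BW_dwaaR_pWaaT	BW_dwaaR_pWaaTW	BW_dwaaR_pWaaX
PilVA	BD	0.0000021	BD	0.0038	BD	0.0000012	BD	BD	BD	BD	BD	0.00000084	0.00000013	BD	0.000000068	BD	BD	BD	BD	0.00000009	BD	0.000025	BD	BD	BD
PilVA'	0.022	0.00037	0.0071	0.0084	0.00035	BD	0.0026	0.001	0.0039	0.00042	0.0026	0.0016	0.00037	0.000059	BD	BD	BD	BD	0.00000012	0.0048	0.031	0.026	0.011	0.028	0.0095
PilVB	0.000022	BD	0.016	0.0000046	BD	BD	0.000017	0.00000042	0.0000013	BD	BD	0.000019	0.000000078	BD	BD	BD	0.0000025	BD	BD	0.00033	BD	BD	0.00000012	BD	BD
PilVB'	BD	0.00003	BD	0.0000019	0.015	0.0000035	BD	0.00000086	0.00000056	BD	BD	0.00000013	BD	0.00000055	BD	0.0000008	BD	BD	BD	BD	0.00000048	BD	BD	0.000000055	BD
PilVC	0.0014	0.00000023	BD	BD	0.00000068	BD	BD	BD	BD	0.0000059	0.00074	0.00000097	0.015	0.0038	0.0021	BD	BD	0.00000099	0.000028	0.0021	0.0012	0.0085	BD	BD	BD
PilVC'	0.0091	0.021	0.014	BD	0.013	BD	0.026	0.0042	0.0000086	0.00000032	0.0047	BD	0.00041	0.004	0.0026	0.000000035	BD	BD	BD	0.0097	0.015	0.0015	BD	0.0056	0.00081
PilVD	BD	0.016	BD	BD	BD	BD	BD	BD	BD	BD	BD	BD	BD	BD	BD	BD	0.000015	0.000000054	BD	0.0000025	0.0000001	BD	BD	BD	BD
PilVD'	BD	BD	0.000011	0.0035	BD	0.00002	BD	BD	0.000019	BD	BD	0.00000011	0.000000064	BD	BD	BD	BD	BD	BD	BD	0.0025	0.0000044	BD	BD	0.0000093
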