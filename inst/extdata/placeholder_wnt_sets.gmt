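wnt_negative_regulators	placeholder set: wnt_negative_regulators	AXIN2	NKD1	APCDD1	NOTUM	DKK4
wnt_global_responsive	placeholder set: wnt_global_responsive	AXIN2	NKD1	APCDD1	NOTUM	DKK4	BG001	BG002	BG003	BG004	BG005	BG006	BG007	BG008	BG009	BG010
wnt_stem_cell	placeholder set: wnt_stem_cell	BG011	BG012	BG013	BG014	BG015	BG016	BG017	BG018
wnt_proliferative	placeholder set: wnt_proliferative	BG019	BG020	BG021	BG022	BG023	BG024	BG025	BG026
caf_signature	placeholder set: caf_signature	CAF1	CAF2	CAF3	CAF4	CAF5	CAF6	CAF7	CAF8
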