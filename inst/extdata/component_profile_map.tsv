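profile_set	profile_name	category
MPF_T	VirB4	VirB4
MPF_F	VirB4	VirB4
MPF_I	VirB4	VirB4
MPF_G	VirB4	VirB4
MPF_C	VirB4	VirB4
MPF_B	VirB4	VirB4
MPF_FA	VirB4	VirB4
MPF_FATA	VirB4	VirB4
MPF_T	VirD4	T4CP
MPF_FATA	TcpA	T4CP
MPF_FATA	TrsD	TrsD
MPF_FATA	TrsG	VirB1
MPF_FATA	CD419	VirB1
MPF_T	VirB1	VirB1
MPF_B	TraE	VirB2
MPF_G	Tfc9	VirB2
MPF_G	Tfc10	VirB2
MPF_I	TraQ	VirB2
MPF_I	TraR	VirB2
MPF_T	VirB2	VirB2
Pfam	PF04956.16	VirB2
Pfam	PF18895.3	VirB2
MPF_B	TraF	VirB3
MPF_C	Alr705	VirB3
MPF_F	TraL	VirB3
MPF_FATA	PrgI	VirB3
MPF_FATA	TrsC	VirB3
MPF_G	Tfc11	VirB3
MPF_I	TraP	VirB3
MPF_T	VirB3	VirB3
MPF_FATA	PrgH	VirB6
MPF_T	VirB6	VirB6
MPF_F	TraE	VirB8
MPF_FATA	PrgL	VirB8
MPF_T	VirB8	VirB8
MPF_FATA	PrgC	VirB9
MPF_T	VirB9	VirB9
MPF_T	VirB10	VirB10
MPF_F	TraB	VirB10
MPF_FATA	PrgF	PrgF
MPF_FATA	TrsJ	TrsJ
MPF_FATA	Gbs1347	Gbs1347
MPF_FATA	Gbs1350	Gbs1350
MPF_FA	Orf17	Orf17
MOBscan	MOBC	Relaxase_MOBC
MOBscan	MOBM	Relaxase_MOBM
MOBscan	MOBP	Relaxase_MOBP
MOBscan	MOBV	Relaxase_MOBV
MOBscan	MOBQ	Relaxase_MOBQ
MOBscan	MOBT	Relaxase_MOBT
MOBscan	MOBF	Relaxase_MOBF
MOBscan	MOBH	Relaxase_MOBH
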