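sample_id	haplogroup	ethnic_group	b	t	g	r	Gr	y	P4	P5	P6	P7	P8	events
R001	J-M172	Turkmen	4	2	3	4	1	2	2	2	2	2	2	.
R002	R-M269	Turkmen	4	2	3	4	1	2	2	2	2	2	2	.
R003	R-M198	Turkmen	4	2	3	4	1	2	2	2	2	2	2	.
R004	G-M201	Turkmen	4	2	3	4	1	2	2	2	2	2	2	.
R005	J-L26*	Persian	5	2	5	6	2	3	2	2	2	2	2	r2/r3 inversion; b2/b3 duplication; Gr micro-duplication
R006	J-M47	Bakhtiari	10	2	12	16	4	8	2	2	2	2	2	b2/b4 duplication; b2/b4 duplication
R007	E-M35	Turkmen	4	2	3	4	1	2	2	2	2	2	2	.
R008	C-M217	Bakhtiari	3	0	3	4	1	3	2	2	2	2	2	g1/g2 duplication; b1/b3 deletion
R009	T-M70	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R010	L-M20	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R011	Q-M25	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R012	J-L26*	Kurd	5	2	5	6	1	3	2	2	2	2	2	r2/r3 inversion; b2/b3 duplication
R013	J-M267	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R014	R-M198	Azeri	5	2	4	6	2	3	2	2	2	2	2	gr/gr duplication
R015	R-M269	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R016	J-M172	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R017	R-M269	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R018	R-M198	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R019	J-M267	Arab	4	2	3	4	1	3	2	2	2	2	2	y micro-duplication
R020	G-M201	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R021	E-M35	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R022	T-M70	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R023	L-M20	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R024	Q-M25	Qashqai	4	2	3	4	1	2	2	2	2	2	2	.
R025	J-M267	Bakhtiari	4	2	3	4	1	2	2	2	2	2	2	.
R026	R-M269	Bakhtiari	4	2	3	4	1	2	2	2	2	2	2	.
R027	J-M172	Bakhtiari	4	2	3	4	1	2	2	2	2	2	2	.
R028	R-M269	Bakhtiari	4	2	3	4	1	2	2	2	2	2	2	.
R029	R-M198	Bakhtiari	4	2	3	4	1	2	2	2	2	2	2	.
R030	G-M201	Bakhtiari	4	2	3	4	1	2	2	2	2	2	2	.
R031	E-M35	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R032	T-M70	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R033	T-L162	Persian	4	3	3	4	1	2	2	2	2	2	2	t micro-duplication
R034	L-M20	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R035	Q-M25	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R036	J-M267	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R037	R-M269	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R038	J-M172	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R039	R-M269	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R040	R-M198	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R041	G-M201	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R042	E-M34	Lur	4	2	3	5	2	2	2	2	2	2	2	r micro-duplication; Gr micro-duplication
R043	E-M35	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R044	T-M70	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R045	L-M20	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R046	Q-M25	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R047	J-M267	Persian	4	2	3	4	1	2	2	2	2	2	2	.
R048	R-M269	Azeri	4	2	3	4	1	2	2	2	2	2	2	.
R049	J-M172	Azeri	4	2	3	4	1	2	2	2	2	2	2	.
R050	R-M269	Azeri	4	2	3	4	1	2	2	2	2	2	2	.
R051	R-M198	Azeri	4	2	3	4	1	2	2	2	2	2	2	.
R052	G-M201	Azeri	4	2	3	4	1	2	2	2	2	2	2	.
R053	T-Y11151	Qashqai	4	2	3	4	1	2	3	2	2	2	2	P4 arm duplication
R054	E-M35	Azeri	4	2	3	4	1	2	2	2	2	2	2	.
R055	T-M70	Azeri	4	2	3	4	1	2	2	2	2	2	2	.
R056	J-M47	Lur	5	2	5	6	1	3	2	2	2	2	2	r2/r3 inversion; b2/b3 duplication
R057	L-M20	Azeri	4	2	3	4	1	2	2	2	2	2	2	.
R058	T-Y11151	Qashqai	4	2	3	4	1	2	3	2	2	2	2	P4 arm duplication
R059	T-Y11151	Qashqai	4	2	3	4	1	2	3	2	2	2	2	P4 arm duplication
R060	Q-M25	Azeri	4	2	3	4	1	2	2	2	2	2	2	.
R061	N-L666	Turkmen	4	2	2	4	2	2	2	2	2	2	2	r2/r3 inversion; b2/b3 deletion; b2/b3 rescue
R062	J-M267	Azeri	4	2	3	4	1	2	2	2	2	2	2	.
R063	N-M46	Turkmen	3	2	1	2	1	1	2	2	2	2	2	r2/r3 inversion; b2/b3 deletion
R064	N-L666	Turkmen	4	2	2	4	2	2	2	2	2	2	2	r2/r3 inversion; b2/b3 deletion; b2/b3 rescue
R065	N-L666	Turkmen	4	2	2	4	2	2	2	2	2	2	2	r2/r3 inversion; b2/b3 deletion; b2/b3 rescue
R066	R-M269	Kurd	4	2	3	4	1	2	2	2	2	2	2	.
R067	J-M172	Kurd	4	2	3	4	1	2	2	2	2	2	2	.
R068	R-M269	Kurd	4	2	3	4	1	2	2	2	2	2	2	.
R069	R-M198	Kurd	4	2	3	4	1	2	2	2	2	2	2	.
R070	G-M201	Kurd	4	2	3	4	1	2	2	2	2	2	2	.
R071	E-M35	Kurd	4	2	3	4	1	2	2	2	2	2	2	.
R072	T-M70	Kurd	4	2	3	4	1	2	2	2	2	2	2	.
R073	L-M20	Lur	4	2	3	4	1	2	2	2	2	2	2	.
R074	Q-M25	Lur	4	2	3	4	1	2	2	2	2	2	2	.
R075	J-M67	Azeri	5	2	5	6	2	3	2	2	2	2	2	r2/r3 inversion; b2/b3 duplication; Gr micro-duplication
R076	J-M267	Lur	4	2	3	4	1	2	2	2	2	2	2	.
R077	J-L24	Kurd	2	0	2	2	1	2	2	2	2	2	2	b1/b3 deletion; non-NAHR grey gain
R078	R-M269	Lur	4	2	3	4	1	2	2	2	2	2	2	.
R079	J-M172	Lur	4	2	3	4	1	2	2	2	2	2	2	.
R080	R-M269	Arab	4	2	3	4	1	2	2	2	2	2	2	.
R081	R-M198	Arab	4	2	3	4	1	2	2	2	2	2	2	.
R082	G-M201	Arab	4	2	3	4	1	2	2	2	2	2	2	.
R083	T-L162	Persian	5	2	5	6	1	3	2	2	2	2	2	r2/r3 inversion; b2/b3 duplication
R084	E-M35	Arab	4	2	3	4	1	2	2	2	2	2	2	.
R085	T-M70	Arab	4	2	3	4	1	2	2	2	2	2	2	.
R086	G-M3406	Persian	5	2	4	6	2	3	2	2	2	2	2	gr/gr duplication
R091	J-M67	Persian	5	2	5	6	2	3	2	2	2	2	2	r2/r3 inversion; b2/b3 duplication; Gr micro-duplication
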