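sample_id	clan	dys385_duplicated
Q001	ClanA	1
Q002	ClanA	1
Q003	ClanA	1
Q004	ClanA	1
Q005	ClanA	1
Q006	ClanA	1
Q007	ClanA	1
Q008	ClanA	1
Q009	ClanA	1
Q010	ClanA	1
Q011	ClanA	1
Q012	ClanA	1
Q013	ClanA	1
Q014	ClanA	1
Q015	ClanA	1
Q016	ClanA	1
Q017	ClanA	1
Q018	ClanA	1
Q019	ClanA	1
Q020	ClanA	1
Q021	ClanA	1
Q022	ClanA	1
Q023	ClanA	0
Q024	ClanA	0
Q025	ClanA	0
Q026	ClanA	0
Q027	ClanA	0
Q028	ClanA	0
Q029	ClanA	0
Q030	ClanA	0
Q031	ClanA	0
Q032	ClanA	0
Q033	ClanA	0
Q034	ClanA	0
Q035	ClanA	0
Q036	ClanA	0
Q037	ClanA	0
Q038	ClanA	0
Q039	ClanA	0
Q040	ClanB	0
Q041	ClanB	0
Q042	ClanB	0
Q043	ClanB	0
Q044	ClanB	0
Q045	ClanB	0
Q046	ClanB	0
Q047	ClanB	0
Q048	ClanB	0
Q049	ClanB	0
Q050	ClanC	0
Q051	ClanC	0
Q052	ClanC	0
Q053	ClanC	0
Q054	ClanC	0
Q055	ClanC	0
Q056	ClanC	0
Q057	ClanC	0
Q058	ClanC	0
Q059	ClanD	0
Q060	ClanD	0
Q061	ClanD	0
Q062	ClanD	0
Q063	ClanD	0
Q064	ClanD	0
Q065	ClanD	0
Q066	ClanD	0
Q067	ClanE	0
Q068	ClanE	0
Q069	ClanE	0
Q070	ClanE	0
Q071	ClanE	0
Q072	ClanE	0
Q073	ClanE	0
Q074	ClanF	0
Q075	ClanF	0
Q076	ClanF	0
Q077	ClanF	0
Q078	ClanF	0
Q079	ClanF	0
Q080	ClanG	0
Q081	ClanG	0
Q082	ClanG	0
Q083	ClanG	0
Q084	ClanG	0
Q085	ClanH	0
Q086	ClanH	0
Q087	ClanH	0
Q088	ClanH	0
Q089	ClanH	0
Q090	ClanI	0
Q091	ClanI	0
Q092	ClanI	0
Q093	ClanI	0
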