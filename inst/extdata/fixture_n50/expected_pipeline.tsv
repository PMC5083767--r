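patient_id	index_atc	age_group	period	has_episode	titration	dose	status
P00001	N06AB05	preteen	P1994_2003	TRUE	up	1	valid
P00002	N06AB03	teen	P2004_2009	TRUE	same	1	valid
P00003	N06AB04	preteen	P2010_2014	TRUE	same	0.5	valid
P00004	N06AX05	preteen	P1994_2003	FALSE		0.1666666667	valid
P00006	N06AA10	teen	P1994_2003	TRUE	up	0.3333333333	valid
P00007	N06AB04	teen	P2010_2014	TRUE	same	0.5	valid
P00008	N06AB05	teen	P1994_2003	TRUE	same	1	valid
P00009	N06AB04	teen	P2004_2009	TRUE	same	1	valid
P00010	N06AB04	teen	P2004_2009	FALSE		1	valid
P00011	N06AB04	child	P2010_2014	TRUE	same	0.5	valid
P00012	N06AX11	teen	P1994_2003	FALSE		0.5	valid
P00013	N06AB05	preteen	P1994_2003	TRUE	same	0.5	valid
P00014	N06AA09	teen	P1994_2003	TRUE	same	0.3333333333	valid
P00015	N06AB04	teen	P2004_2009	FALSE		0.25	valid
P00016	N06AB05	teen	P1994_2003	FALSE		1	valid
P00017	N06AB04	preteen	P2010_2014	FALSE		0.5	valid
P00018	N06AB03	teen	P1994_2003	TRUE	down	0.5	valid
P00019	N06AA09	teen	P1994_2003	FALSE		0.2	valid
P00020	N06AB04	teen	P2004_2009	TRUE	up	1	valid
P00021	N06AB08	preteen	P1994_2003	TRUE	up	0.5	valid
P00022	N06AB04	teen	P1994_2003	TRUE	same	0.25	valid
P00023	N06AX11	child	P2010_2014	TRUE	same	1	valid
P00024	N06AX03	teen	P1994_2003	TRUE	up	0.25	valid
P00025	N06AA04	preteen	P1994_2003	FALSE		0	too_low
P00026	N06AB06	teen	P2010_2014	TRUE	same	1	valid
P00027	N06AB04	teen	P2010_2014	TRUE	up	0.5	valid
P00028	N06AX03	teen	P1994_2003	TRUE	up	0.25	valid
P00029	N06AX11	preteen	P2010_2014	FALSE		0.5	valid
P00030	N06AB03	preteen	P2004_2009	TRUE	up	0.5	valid
P00031	N06AB03	teen	P2004_2009	TRUE	same	1	valid
P00032	N06AA02	teen	P1994_2003	FALSE		0.5	valid
P00033	N06AB06	teen	P1994_2003	FALSE		0.5	valid
P00034	N06AB04	teen	P2010_2014	FALSE		1	valid
P00035	N06AB04	teen	P2004_2009	TRUE	up	1	valid
P00036	N06AX16	teen	P1994_2003	FALSE		1	valid
P00037	N06AB03	child	P2010_2014	TRUE	same	1	valid
P00038	N06AB03	teen	P2010_2014	FALSE		0.5	valid
P00039	N06AB04	teen	P2004_2009	FALSE		1	valid
P00040	N06AB06	teen	P2010_2014	FALSE		1	valid
P00041	N06AA02	child	P1994_2003	TRUE	same	0.2	valid
P00042	N06AB06	teen	P2004_2009	TRUE	same	1	valid
P00043	N06AA10	preteen	P1994_2003	TRUE	up	0.3333333333	valid
P00044	N06AB05	teen	P1994_2003	FALSE		1	valid
P00045	N06AB08	teen	P1994_2003	TRUE	same	0.25	valid
P00046	N06AB08	teen	P1994_2003	FALSE		1	valid
P00047	N06AB05	teen	P1994_2003	FALSE		0	too_low
P00048	N06AB10	teen	P2004_2009	TRUE	up	0.5	valid
P00049	N06AB08	teen	P1994_2003	FALSE		0	too_low
P00050	N06AX11	child	P2004_2009	TRUE	same	0.5	valid
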