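patient_id	label	index_atc	dose_error	start_dose	has_maintenance	maintenance_dose	titration	sex	age_group	period	prescriber
P00001	included	N06AB05	none	1	TRUE	2	up	F	preteen	P1994_2003	specialist
P00002	included	N06AB03	none	1	TRUE	1	same	M	teen	P2004_2009	GP
P00003	included	N06AB04	none	0.5	TRUE	0.5	same	F	preteen	P2010_2014	specialist
P00004	included	N06AX05	none	0.166666666666667	FALSE			F	preteen	P1994_2003	GP
P00005	bedwetting	N06AA09	none	0.1	FALSE			M	child	P1994_2003	GP
P00006	included	N06AA10	none	0.333333333333333	TRUE	0.666666666666667	up	M	teen	P1994_2003	GP
P00007	included	N06AB04	none	0.5	TRUE	0.5	same	F	teen	P2010_2014	specialist
P00008	included	N06AB05	none	1	TRUE	1	same	M	teen	P1994_2003	GP
P00009	included	N06AB04	none	1	TRUE	1	same	F	teen	P2004_2009	GP
P00010	included	N06AB04	none	1	FALSE			M	teen	P2004_2009	GP
P00011	included	N06AB04	none	0.5	TRUE	0.5	same	M	child	P2010_2014	GP
P00012	included	N06AX11	none	0.5	FALSE			F	teen	P1994_2003	GP
P00013	included	N06AB05	none	0.5	TRUE	0.5	same	M	preteen	P1994_2003	GP
P00014	included	N06AA09	none	0.333333333333333	TRUE	0.333333333333333	same	M	teen	P1994_2003	GP
P00015	included	N06AB04	none	0.25	FALSE			F	teen	P2004_2009	specialist
P00016	included	N06AB05	none	1	FALSE			M	teen	P1994_2003	GP
P00017	included	N06AB04	none	0.5	FALSE			M	preteen	P2010_2014	specialist
P00018	included	N06AB03	none	0.5	TRUE	0.25	down	M	teen	P1994_2003	GP
P00019	included	N06AA09	none	0.2	FALSE			M	teen	P1994_2003	GP
P00020	included	N06AB04	none	1	TRUE	2	up	F	teen	P2004_2009	specialist
P00021	included	N06AB08	none	0.5	TRUE	1	up	M	preteen	P1994_2003	GP
P00022	included	N06AB04	none	0.25	TRUE	0.25	same	M	teen	P1994_2003	specialist
P00023	included	N06AX11	none	1	TRUE	1	same	M	child	P2010_2014	specialist
P00024	included	N06AX03	none	0.25	TRUE	0.5	up	F	teen	P1994_2003	specialist
P00025	included	N06AA04	zero		FALSE			M	preteen	P1994_2003	GP
P00026	included	N06AB06	none	1	TRUE	1	same	F	teen	P2010_2014	GP
P00027	included	N06AB04	none	0.5	TRUE	1	up	F	teen	P2010_2014	specialist
P00028	included	N06AX03	none	0.25	TRUE	0.5	up	M	teen	P1994_2003	GP
P00029	included	N06AX11	none	0.5	FALSE			M	preteen	P2010_2014	specialist
P00030	included	N06AB03	none	0.5	TRUE	1	up	M	preteen	P2004_2009	specialist
P00031	included	N06AB03	none	1	TRUE	1	same	F	teen	P2004_2009	specialist
P00032	included	N06AA02	none	0.5	FALSE			M	teen	P1994_2003	GP
P00033	included	N06AB06	none	0.5	FALSE			M	teen	P1994_2003	GP
P00034	included	N06AB04	none	1	FALSE			M	teen	P2010_2014	specialist
P00035	included	N06AB04	none	1	TRUE	2	up	M	teen	P2004_2009	GP
P00036	included	N06AX16	none	1	FALSE			M	teen	P1994_2003	specialist
P00037	included	N06AB03	none	1	TRUE	1	same	F	child	P2010_2014	specialist
P00038	included	N06AB03	none	0.5	FALSE			F	teen	P2010_2014	specialist
P00039	included	N06AB04	none	1	FALSE			M	teen	P2004_2009	GP
P00040	included	N06AB06	none	1	FALSE			F	teen	P2010_2014	specialist
P00041	included	N06AA02	none	0.2	TRUE	0.2	same	M	child	P1994_2003	GP
P00042	included	N06AB06	none	1	TRUE	1	same	F	teen	P2004_2009	specialist
P00043	included	N06AA10	none	0.333333333333333	TRUE	0.666666666666667	up	F	preteen	P1994_2003	specialist
P00044	included	N06AB05	none	1	FALSE			F	teen	P1994_2003	GP
P00045	included	N06AB08	none	0.25	TRUE	0.25	same	F	teen	P1994_2003	GP
P00046	included	N06AB08	none	1	FALSE			M	teen	P1994_2003	GP
P00047	included	N06AB05	zero		FALSE			M	teen	P1994_2003	GP
P00048	included	N06AB10	none	0.5	TRUE	1	up	F	teen	P2004_2009	specialist
P00049	included	N06AB08	zero		FALSE			F	teen	P1994_2003	GP
P00050	included	N06AX11	none	0.5	TRUE	0.5	same	F	child	P2004_2009	specialist
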