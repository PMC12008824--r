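sex	interval	first_age	second_age	is_reference	cases	cases_change_pct	deaths	deaths_change_pct	ypll	ypll_change_pct	dalys	dalys_change_pct
male	NA	NA	NA	FALSE	11862	294	5264	414	69173	347	126843	253
male	10	45	55	FALSE	3788	26	1384	35	15562	0	38331	7
male	10	50	60	TRUE	3012	NA	1024	NA	15487	NA	35928	NA
male	10	55	65	FALSE	3262	8	1101	8	20428	31	47143	31
male	10	60	70	FALSE	3945	31	1363	33	27723	79	60295	68
male	15	45	60	FALSE	3210	7	1077	5	14057	-9	34294	-5
male	15	50	65	FALSE	3035	1	983	-4	16391	6	39568	10
male	15	55	70	FALSE	3517	17	1168	14	22020	42	49230	37
male	20	45	65	FALSE	3543	18	1156	13	17033	10	42801	19
male	20	50	70	FALSE	3600	20	1175	15	19703	27	46651	30
female	NA	NA	NA	FALSE	8899	291	3795	397	54720	281	101846	191
female	10	45	55	FALSE	3225	42	1190	56	14073	-2	36454	4
female	10	50	60	FALSE	2413	6	839	10	12365	-14	30514	-13
female	10	55	65	TRUE	2276	NA	763	NA	14378	NA	35022	NA
female	10	60	70	FALSE	2500	10	822	8	18624	30	41670	19
female	15	45	60	FALSE	2614	15	895	17	11862	-17	30717	-12
female	15	50	65	FALSE	2213	-3	724	-5	12207	-15	31266	-11
female	15	55	70	FALSE	2341	3	744	-2	15143	5	35275	1
female	20	45	65	FALSE	2598	14	850	11	13207	-8	34946	0
female	20	50	70	FALSE	2508	10	784	3	14337	0	34382	-2
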