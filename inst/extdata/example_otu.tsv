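#OTU ID	S01P01	S01P02	S01P03	S02P01	S02P02	S02P03	S03P01	S03P02	S03P03	S04P01	S04P02	S04P03	taxonomy
OTU0001	7	18	14	64	97	80	1	3	1	0	0	0	k__Bacteria; p__Actinobacteria; c__unclassified
OTU0002	2514	2517	2510	1617	1658	1591	269	239	259	15	20	12	k__Bacteria; p__Verrucomicrobia; c__unclassified
OTU0003	89	74	76	104	97	100	101	114	103	248	238	239	k__Bacteria; p__Proteobacteria; c__unclassified
OTU0004	644	639	594	328	326	368	208	242	239	267	245	242	k__Bacteria; p__Proteobacteria; c__unclassified
OTU0005	0	0	0	128	132	130	3805	3750	3696	6949	7009	6940	k__Bacteria; p__Acidobacteria; c__unclassified
OTU0006	27	49	46	1671	1759	1671	2778	2819	2855	211	192	206	k__Bacteria; p__Acidobacteria; c__unclassified
OTU0007	1789	1792	1867	1628	1672	1689	2088	2000	2037	4140	4175	4205	k__Bacteria; p__Proteobacteria; c__unclassified
OTU0008	0	0	0	5	2	4	58	48	61	265	288	267	k__Bacteria; p__Acidobacteria; c__unclassified
OTU0009	1251	1311	1244	162	159	149	0	0	0	0	0	0	k__Bacteria; p__Acidobacteria; c__unclassified
OTU0010	574	604	569	161	186	183	62	56	55	16	22	16	k__Bacteria; p__Proteobacteria; c__unclassified
OTU0011	89	76	90	1600	1553	1545	2843	2891	2872	667	669	708	k__Bacteria; p__Acidobacteria; c__unclassified
OTU0012	0	0	0	0	1	0	95	66	85	1313	1356	1395	k__Bacteria; p__Acidobacteria; c__unclassified
OTU0013	66	72	72	112	92	131	22	17	22	1	1	0	k__Bacteria; p__Actinobacteria; c__unclassified
OTU0014	0	0	0	7	3	7	998	1047	1010	4535	4511	4471	k__Bacteria; p__Acidobacteria; c__unclassified
OTU0015	1928	2044	1857	4800	4854	4783	3672	3780	3756	1080	1066	1099	k__Bacteria; p__Verrucomicrobia; c__unclassified
OTU0016	7	5	9	347	348	324	413	374	403	14	19	20	k__Bacteria; p__Acidobacteria; c__unclassified
OTU0017	295	337	332	965	950	970	67	62	65	0	0	0	k__Bacteria; p__Acidobacteria; c__unclassified
OTU0018	86	97	106	665	603	631	1382	1342	1375	1224	1178	1238	k__Bacteria; p__Verrucomicrobia; c__unclassified
OTU0019	761	767	810	795	767	792	97	104	117	1	3	5	k__Bacteria; p__Acidobacteria; c__unclassified
OTU0020	9290	9071	9244	3644	3728	3795	1689	1761	1687	1126	1086	1014	k__Bacteria; p__Verrucomicrobia; c__unclassified
OTU0021	1907	1913	1952	1971	1891	1958	1356	1315	1349	922	894	921	k__Bacteria; p__Proteobacteria; c__unclassified
OTU0022	504	495	483	348	336	313	72	66	63	9	2	3	k__Bacteria; p__Verrucomicrobia; c__unclassified
OTU0023	450	436	482	415	401	465	101	108	86	2	9	6	k__Bacteria; p__Verrucomicrobia; c__unclassified
OTU0024	2300	2268	2277	1389	1337	1316	1088	1120	1138	1733	1726	1716	k__Bacteria; p__Proteobacteria; c__unclassified
OTU0025	422	415	366	2074	2048	2005	1735	1676	1666	262	291	277	k__Bacteria; p__Verrucomicrobia; c__unclassified
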