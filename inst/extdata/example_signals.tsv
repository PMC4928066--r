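probe_id	category	S01P01	S01P02	S01P03	S02P01	S02P02	S02P03	S03P01	S03P02	S03P03	S04P01	S04P02	S04P03
probe0001	FTHFS	1349.64199480634	341.806423894797	932.841513118476	622.848836503431	NA	293.323657447876	525.209087102736	655.287537785282	636.891563634408	560.897461503461	587.313998679071	455.886065751831
probe0002	FBPase	597.366790127818	220.88872030556	434.403110245279	201.642445668457	197.326178354087	135.518999417707	289.197525897337	255.567936989553	307.036560588712	247.037170106031	253.462399279937	201.768707637093
probe0003	Rubisco	756.104737846399	206.349199122684	442.136319601272	377.897496273005	231.446792507983	201.197818301076	339.717157858814	NA	385.047084001154	NA	337.114025248909	243.886892715842
probe0004	cellobiase	514.703908951675	NA	391.116396020597	229.314155769092	154.591053135	138.642986373747	227.460719789433	235.177940885714	258.403249324205	NA	314.481842222176	179.928884282988
probe0005	endoglucanase	451.627782475616	135.128981092994	323.124087572789	NA	134.926875153794	132.545912636824	NA	291.495721507071	256.388332984178	NA	257.516113199573	188.889862148298
probe0006	chitinase	601.580786320805	NA	544.311016596612	344.481409238958	238.402805583686	NA	330.892951695604	352.097863406766	392.032343831074	272.862559650451	447.293807827376	259.153425327931
probe0007	mannanase	616.984166920456	198.263029331208	479.80821318867	362.548292567413	189.606724169478	149.037292098854	282.573572285162	297.974473882713	358.157310855058	293.706113602055	448.626372200414	213.49399521598
probe0008	xylanase	991.592863477827	NA	550.6405670363	411.866688793415	281.257172399676	243.600373086301	399.648891878636	359.021545158641	NA	NA	563.37145278314	323.053235213241
probe0009	phenol_oxidase	3867.36852220808	982.629187599383	2886.24089083241	2144.60747058819	1437.17452979875	1075.38156106489	1889.40064455037	2416.59398703361	2129.42186832668	NA	2024.63338818853	1551.73199669786
probe0010	amyA	867.32245815912	232.857410528018	585.209526047832	386.392834345722	244.269248483091	196.654461495476	414.127628142762	358.21315786832	450.206706674746	366.205211319148	NA	315.610252973335
probe0011	ureC	385.117344776597	117.171452307154	303.243277201668	155.811170053836	128.78817590663	NA	161.538132875454	167.711627005194	184.148586386467	148.50720955655	239.002715755479	179.309776497853
probe0012	narG	1003.58631745016	360.337824431713	878.521665366702	489.099587182726	380.137823779328	NA	432.501415688034	634.390732100245	508.845146934263	538.395709646249	752.481256772163	443.522128036161
probe0013	nirS_K	2437.71298105529	754.730213724616	1595.15489255837	1062.47545939318	837.639029705316	622.986451184535	1249.20522393997	1245.25315629594	1407.76764834919	1282.17005355061	1504.21879619065	1039.99773712078
probe0014	nosZ	NA	893.90717943329	2800.71532054621	NA	NA	807.266553214498	1376.27900509601	1560.1042681813	1730.85810353742	1909.74629729222	NA	1305.17773998946
probe0015	nifH	1545.89011763454	469.116345894305	1023.81910921808	NA	489.814884369243	411.864922681175	539.112169075785	724.315469695544	771.21680912348	NA	834.629302098894	598.927629355706
probe0016	phytase	732.742971718286	202.88149487652	591.819237868326	360.096769249008	246.596267853224	241.847324087286	350.615551722018	342.859198725766	448.538700744515	335.825317943315	515.151868289483	281.839265418133
probe0017	ppx	NA	217.72378971218	668.64291091027	427.02768120131	NA	290.252853760393	423.927406669009	468.292364227813	667.35981478936	375.616145713944	616.612198118152	368.969986374137
probe0018	ppk	838.596735377651	266.710663562078	560.835661361377	409.586422846325	NA	237.170849148242	337.528838262872	382.199271731643	414.737724295462	458.807876416377	538.421835445514	262.351128705457
probe0019	FTHFS	NA	6178.68056250989	15541.1439146797	8097.46508663135	6227.69462872507	4794.16282624356	9038.16482574234	NA	10374.4109766564	9153.15241447389	11758.9877139696	6400.42290288807
probe0020	FBPase	NA	77.9402846009491	NA	97.0969616087519	91.0308067539528	60.7545025747777	95.8455791758833	120.193562460323	126.611587857049	114.242426603707	140.303291379272	113.028090412608
probe0021	Rubisco	NA	102.376661742942	289.517723405386	164.156142708357	121.474322029954	103.526685955273	162.058119702891	178.547554364446	179.961885403175	147.338373521147	192.264250379056	138.61897297314
probe0022	cellobiase	937.6029774113	330.616088899719	882.158721033964	615.543225729105	339.209852549455	NA	499.194098216927	546.77525696529	646.268995392662	619.786483099003	671.260868004645	365.350377277481
probe0023	endoglucanase	821.485092444103	213.226557262765	607.046402352428	450.584520253929	250.926502738083	233.060117950159	375.078863980704	380.780667252253	427.308040829303	379.144071994213	516.607372531184	334.995577025365
probe0024	chitinase	729.456767402515	191.629226074235	529.931477036305	257.907895889685	240.979132172512	187.958266134828	NA	337.640085017959	292.967690957822	309.958043141503	411.319941157368	280.553705565852
probe0025	mannanase	729.779230375902	NA	563.173593654472	NA	210.282308105044	182.194036580107	NA	349.012712962641	312.188434596365	264.224403263332	435.490869069773	NA
probe0026	xylanase	996.338570036309	246.292117295059	604.242181079066	404.044841332994	272.025044534268	233.547262602523	378.411334134587	487.906844932306	NA	439.26642271684	650.588035703616	374.150888968067
probe0027	phenol_oxidase	468.281311482384	NA	324.214347829129	NA	146.257385039828	NA	244.747135589109	274.948394777792	234.556505161504	197.35950360853	278.099992894923	174.357781419559
probe0028	amyA	1172.89544704955	306.515046467088	796.924047101662	405.266464189297	348.79145620622	308.980268811488	NA	444.34890249599	NA	483.486399819012	665.310921449292	NA
probe0029	ureC	3315.15708181788	1046.4102970131	2274.17279257625	1540.32891115658	1004.61768352019	801.523474944936	1626.67486697291	1410.13212590421	1966.1937912454	1321.33547612324	1935.68222819065	NA
probe0030	narG	1000.76262575249	329.256627869715	688.323910909595	535.665539449354	382.423310140356	306.984696395068	465.868521186514	NA	551.764009740819	487.714877185182	696.031513916882	NA
probe0031	nirS_K	910.499748094338	266.974798249115	859.706098153808	NA	339.772655602062	281.456600159268	NA	568.96171650468	NA	447.918921216281	533.296887289181	418.06267548733
probe0032	nosZ	429.976406522001	153.005158276025	397.778418475151	241.973141821193	180.460180541904	143.497767940994	226.440417090499	214.395350696252	301.364703018873	243.933245801409	341.232294916932	192.990805097612
probe0033	nifH	464.93186128618	131.910015635718	343.594492766625	187.938154668881	146.699178206032	96.110465253259	168.363086695257	NA	178.825325268831	190.517557669899	271.407970745203	NA
probe0034	phytase	938.358382348357	370.79250091275	1002.95388455101	509.673913388495	344.727644415985	330.631421953176	511.473994306705	553.300886148221	601.802740927619	512.225284022408	758.669317754437	439.887039026877
probe0035	ppx	459.436849051677	149.260949479412	376.633034163918	264.372934743858	178.229163343643	132.354346012749	226.488868249373	250.308981706628	267.847735347143	196.102126639858	298.173703052703	171.118012524741
probe0036	ppk	1375.05988068486	386.202200916186	747.15215913341	574.487857912003	NA	312.672063388646	NA	682.921996639388	644.695694425974	579.465442667998	968.128152229874	NA
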