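sample_id	site_id	plot_id	latitude	longitude	elevation	pH	plant_shannon
S01P01	site01	plot01	23.0018210284826	111.65794375542	1568.94485465234	0.48749870030203	0.884527703771667
S01P02	site01	plot02	22.9995219616392	111.647258158576	1535.9420877286	0.412467370367617	0.908943897224692
S01P03	site01	plot03	23.0068086576461	111.648231079713	1568.80543770464	0.560781259859916	0.982384091086276
S02P01	site02	plot01	28.6662402746017	111.754248109704	1355.5178285511	1.6574918298021	2.3240041136273
S02P02	site02	plot02	28.6757586653778	111.746920398263	1365.42581409334	1.84187708019058	1.77694123664852
S02P03	site02	plot03	28.666384170725	111.740277741327	1316.10491717202	1.53346721654297	1.3059381048372
S03P01	site03	plot01	34.3392111245686	109.143783736642	1741.00762005322	0.476500041650948	0.620473883544765
S03P02	site03	plot02	34.343633537805	109.150029646799	1674.34870598208	0.817762785282449	0.679608650585057
S03P03	site03	plot03	34.327077204049	109.153095046629	1702.3251961029	0.343866882386935	0.491743075579019
S04P01	site04	plot01	39.9987441947441	111.319851454127	616.872647202763	2.75349211599653	1.91927898475159
S04P02	site04	plot02	39.9993994534397	111.320631633176	569.97364552966	3.33045562417515	1.46505330341379
S04P03	site04	plot03	40.0028646414328	111.31384832821	643.483553234827	3.63585015517506	1.72347133096232
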