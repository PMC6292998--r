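table	origin	target	structural	functional	deg_avg
1	left putamen	left parahippocampal posterior	0.163502106	0.020203011	687.5
1	left putamen	left planum temporale	0.18985185	-0.01262453	625
1	left frontal pole	left putamen	0.28089338	0.15076964	927
1	left frontal pole	left putamen	0.268176361	0.13167174	927
1	left frontal medial	left putamen	0.110934828	0.094022519	790
1	left frontal pole	left putamen	0.478702548	0.21312926	927
1	left frontal pole	left putamen	0.10229685	0.11504351	927
1	left frontal orbital	left putamen	0.355902746	0.32012312	726
1	left frontal pole	left putamen	0.200164537	0.1399255	927
1	left frontal orbital	left putamen	0.23406272	0.19123371	726
1	left frontal pole	left putamen	0.187038633	0.17440578	927
1	right putamen	right heschl's	0.251257875	0.049333889	695
1	right putamen	right parahippocampal posterior	0.240377155	0.027959258	687.5
1	right putamen	right planum polare	0.361161921	0.1971855	655
1	right frontal pole	right putamen	0.135257294	0.2283248	927
1	right frontal pole	right putamen	0.342326336	0.16207665	927
1	left frontal medial	right putamen	0.103986254	0.14005883	790
1	right frontal pole	right putamen	0.174086567	0.13810447	927
1	right frontal orbital	right putamen	0.275009861	0.24960994	726
1	right frontal pole	right putamen	0.289418731	0.11346083	927
1	right temporal pole	right putamen	0.290537649	0.24174925	806.5
1	right frontal pole	right putamen	0.145893171	0.13850855	927
1	right frontal pole	right putamen	0.61517917	0.27000022	927
1	right frontal pole	right putamen	0.175577644	0.10383046	927
1	right temporal pole	right putamen	0.117579801	0.083963864	806.5
2	right lingual	left occipital fusiform	0.264136489	0.73615919	271.6666667
2	left lingual	left occipital fusiform	0.22772869	0.60275624	271.6666667
2	right lingual	left parahippocampal posterior	0.143716534	0.50098513	251.5
2	left lingual	left parahippocampal posterior	0.30761773	0.55396672	251.5
2	right lingual	right occipital fusiform	0.177391911	0.51224682	271.6666667
2	right lingual	right occipital fusiform	0.235064117	0.68679426	271.6666667
2	left lingual	right occipital fusiform	0.02712589	0.61838067	271.6666667
2	right lingual	right parahippocampal posterior	0.33430536	0.51577434	251.5
3	left superior parietal lobule	left superior parietal lobule	0.558669936	0.71112541	3
3	left superior parietal lobule	left superior parietal lobule	0.558669936	0.71112541	3
3	right cingulate anterior	right cingulate anterior	0.605500596	0.53997424	0
3	right juxtapositional lobule	right cingulate anterior	0.596213811	0.71527726	7.75
3	right cingulate anterior	right cingulate anterior	0.605500596	0.53997424	0
3	right juxtapositional lobule	right cingulate posterior	0.521552114	0.55794716	0.5
3	right cingulate anterior	right cingulate posterior	0.631735262	0.58602299	1.5
3	right superior parietal lobule	right superior parietal lobule	0.695758645	0.68872082	3
3	right superior parietal lobule	right superior parietal lobule	0.695758645	0.68872082	3
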