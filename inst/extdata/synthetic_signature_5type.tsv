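gene	CellTypeA	CellTypeB	CellTypeC	CellTypeD	CellTypeE
MK_A_01	93.369253063574433	8.3342721126973629	11.262453445233405	12.193785912822932	13.851176870521158
MK_A_02	87.537373183295131	8.4674824820831418	7.1715769823640585	8.2408595248125494	10.171110555529594
MK_A_03	90.788647131994367	8.9848541142418981	7.1656731097027659	12.788094985298812	13.519309849943966
MK_A_04	101.22976312413812	12.846927756909281	8.8894502865150571	8.9444100181572139	9.4279626826755702
MK_A_05	80.85800914093852	5.3893649112433195	14.424556919839233	11.785928679164499	6.5788010042160749
MK_A_06	111.95041229948401	12.487953861709684	14.626080137677491	12.758250427432358	9.4232463883236051
MK_A_07	84.413404008373618	11.7727683018893	12.398552792146802	6.8786904402077198	14.677336672320962
MK_A_08	101.59193143248558	6.7126433039084077	12.332459057215601	5.2908581891097128	9.8458792944438756
MK_A_09	102.84935589879751	7.6108796382322907	10.357612899970263	6.3571379706263542	7.5245843944139779
MK_A_10	104.75806187838316	10.144129346590489	5.0227296608500183	11.801641781348735	7.5968998018652201
MK_B_01	9.5774177624844015	108.59414773993194	11.089374525472522	14.348229537717998	10.420159408822656
MK_B_02	12.191122516524047	84.932023147121072	13.368015594314784	10.504940843675286	11.498758376110345
MK_B_03	14.346722471527755	92.441984750330448	12.515225626993924	11.01766235427931	8.3641913230530918
MK_B_04	7.5542882434092462	117.82956650480628	9.5273157255724072	6.9699448812752962	5.6094974628649652
MK_B_05	9.6229282254353166	100.00100369565189	10.357899938244373	10.352366105653346	9.5131085021421313
MK_B_06	14.400145227555186	85.409219963476062	10.373766953125596	6.7955573927611113	13.387550334446132
MK_B_07	14.78226428385824	114.77031282149255	5.0138084357604384	9.5188649441115558	10.746373343281448
MK_B_08	6.1748736165463924	88.201984483748674	8.5566595382988453	8.1705335178412497	8.5335037740878761
MK_B_09	9.7499708156101406	117.00183563865721	11.121330901514739	6.1617467040196061	10.474260782357305
MK_B_10	10.60332746244967	115.47014392912388	13.289421305526048	6.8610215676017106	13.927185938227922
MK_C_01	14.040313872974366	5.4298879601992667	85.451833009719849	12.297300966456532	9.8999057058244944
MK_C_02	6.3871016772463918	6.4047909411601722	111.41397768631577	9.1187207121402025	6.7163211316801608
MK_C_03	14.888917289208621	7.1638541505672038	98.132136566564441	9.1404968174174428	10.430309940129519
MK_C_04	14.466682325582951	9.7939856420271099	85.429696775972843	9.8031012900173664	14.614676958881319
MK_C_05	5.8243755809962749	6.9741034228354692	115.40884147398174	9.2749446560628712	8.136838220525533
MK_C_06	10.142117843497545	12.193558376748115	93.468541605398059	6.3649036013521254	13.205145481042564
MK_C_07	8.9020346710458398	5.0788473873399198	92.770964605733752	13.246794063597918	8.0705440044403076
MK_C_08	14.057381309103221	8.7548996461555362	96.151312589645386	10.923042425420135	6.8545358115807176
MK_C_09	9.4696962810121477	10.144077083095908	99.163092281669378	12.943969776388258	5.4834677674807608
MK_C_10	13.360042599961162	5.0157055421732366	94.716072808951139	12.690324257127941	7.4567414727061987
MK_D_01	12.375956177711487	10.816040025092661	14.036345251370221	98.627622704952955	8.5110692214220762
MK_D_02	13.11055141268298	6.579052081797272	11.034740847535431	81.995686115697026	6.5902238176204264
MK_D_03	8.8810828281566501	8.5902830585837364	11.315072989091277	87.494268463924527	8.040979967918247
MK_D_04	11.851697294041514	11.456318784039468	14.373858496546745	119.30637654848397	5.175483247730881
MK_D_05	5.0394833879545331	12.758233626373112	13.504827506840229	93.13096278347075	14.965526792220771
MK_D_06	13.329160802531987	10.636468415614218	10.79820899059996	86.839855620637536	13.043933126609772
MK_D_07	5.0733414688147604	7.3370339861139655	13.214039239101112	99.530195780098438	5.86580601753667
MK_D_08	7.0765897282399237	5.8998051634989679	6.1371860909275711	80.747496467083693	13.699332696851343
MK_D_09	14.066014077980071	5.8561206492595375	12.645077586639673	93.579403348267078	10.545858633704484
MK_D_10	11.117786434479058	8.0521836946718395	11.236134571954608	81.186535023152828	9.2137842183001339
MK_E_01	8.7955924053676426	11.674265146721154	6.4844660670496523	6.9467614381574094	114.68914652243257
MK_E_02	9.3577158497646451	5.0023889658041298	5.8026446658186615	12.841093826573342	109.26830398850143
MK_E_03	5.3743103286251426	7.0856995694339275	9.6406955132260919	6.2887216173112392	92.610431872308254
MK_E_04	14.73539913771674	14.330341273453087	12.793681614566594	6.2908928352408111	95.458160471171141
MK_E_05	9.3175124889239669	14.256447486113757	12.335279595572501	5.7225311128422618	93.297839621081948
MK_E_06	14.575765966437757	12.340943010058254	13.172304444015026	5.5312948348000646	83.591118846088648
MK_E_07	13.877549055032432	8.3307198341935873	6.7016248125582933	10.318744364194572	110.28222410008311
MK_E_08	11.399787694681436	10.150633298326284	14.447203255258501	6.1230824165977538	104.11873988807201
MK_E_09	14.70966610359028	12.439746463205665	7.9362384136766195	12.431877197232097	85.815998902544379
MK_E_10	11.188382073305547	11.191592400427908	6.4907205244526267	12.313154772855341	81.300699338316917
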