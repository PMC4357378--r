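marker_id	pool_set	p1	p0
candidate	1	0.440679661975656	0.422420341397193
null1	1	0.33786200211172	0.432210244223815
null2	1	0.672178063676254	0.654314653934709
null3	1	0.267996149151011	0.37000159314891
null4	1	0.433829952048165	0.466827672266397
null5	1	0.503173949602559	0.326931569884385
candidate	2	0.513949808819433	0.500542065039124
null1	2	0.456928769128884	0.42471221113818
null2	2	0.604403363805582	0.609728874697787
null3	2	0.352193400644172	0.205116641215734
null4	2	0.441219807676007	0.46655678800209
null5	2	0.380224666687759	0.533830311108345
candidate	3	0.537911485868652	0.491911164077772
null1	3	0.27531651308339	0.532081683630236
null2	3	0.622586058647078	0.749791143821395
null3	3	0.282727643239029	0.236017405041227
null4	3	0.459165361412718	0.363145776965799
null5	3	0.394960661261626	0.303917186047436
candidate	4	0.58096124808916	0.361983554020114
null1	4	0.416898857268455	0.450034362179918
null2	4	0.661540723962639	0.452093787753825
null3	4	0.336048430992286	0.358938387652117
null4	4	0.354423282722276	0.373358313068414
null5	4	0.464993687204141	0.39628257903616
candidate	5	0.44649368367559	0.332205192677781
null1	5	0.540403973458581	0.297081057878083
null2	5	0.616909780523474	0.683606711432747
null3	5	0.293837414424184	0.361599202664534
null4	5	0.410431053028318	0.477964316866007
null5	5	0.478445428415683	0.433101067241332
candidate	6	0.629938204610217	0.609397991812683
null1	6	0.44534400389805	0.583723539672094
null2	6	0.648960234339059	0.696268493223006
null3	6	0.280255349262303	0.191473644112081
null4	6	0.486793568428735	0.528238346621657
null5	6	0.439476513494174	0.410892998333659
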