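"cycle","initial","ned","pn_adjuvant","rr_detected","salvage_rt_rr","ned_post_salvage_rr","progression","bsc_bridge","death","alive","attained_age"
0,1,0,0,0,0,0,0,0,0,1,50
1,0,0.980001248724628,0,0,0,0,0,0,0.0199987512753717,0.980001248724628,51
2,0,0.93759157808907,0,0,0,0.00374414317951953,0.0353184246831211,0,0.0233458540482893,0.976654145951711,52
3,0,0.897017190996015,0,0,0,0.00632877619403754,0.0479105927089326,0,0.0487434401010154,0.951256559898985,53
4,0,0.858198665331805,0,0,0,0.00806981740564293,0.0518114481533616,0,0.0819200691091908,0.918079930890809,54
5,0,0.821060015984201,0,0,0,0.00919871752961207,0.0523211869423575,0,0.117420079543829,0.882579920456171,55
6,0,0.784403582642988,0,0,0,0.00987081952328521,0.0513955173915329,0,0.154330080442194,0.845669919557806,56
7,0,0.749383685095919,0,0,0,0.0102233127267552,0.0499090633366359,0,0.19048393884069,0.80951606115931,57
8,0,0.715927259786031,0,0,0,0.0103479238085512,0.0481892954768298,0,0.225535520928588,0.774464479071412,58
9,0,0.683964505097451,0,0,0,0.0103115673099787,0.0463792946744436,0,0.259344632918126,0.740655367081874,59
10,0,0.653428735725212,0,0,0,0.0101629943870205,0.0445472616367532,0,0.291861008251014,0.708138991748986,60
11,0,0.622833068822644,0,0,0,0.00991500690259856,0.0426315159504223,0,0.324620408324334,0.675379591675666,61
12,0,0.5936699909417,0,0,0,0.00961730201055964,0.0407581095863378,0,0.355954597461402,0.644045402538598,62
13,0,0.56587242358687,0,0,0,0.00928871322903621,0.0389388026155844,0,0.385900060568508,0.614099939431492,63
14,0,0.539376429096825,0,0,0,0.00894275004973849,0.0371804790548568,0,0.414500341798579,0.585499658201421,64
15,0,0.514121063580297,0,0,0,0.0085890427584076,0.0354869338601791,0,0.441802959801116,0.558197040198884,65
16,0,0.488219915566486,0,0,0,0.00820367612986325,0.0337335804441727,0,0.469842827859477,0.530157172140523,66
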