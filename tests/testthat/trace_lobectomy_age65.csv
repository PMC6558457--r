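"cycle","initial","ned","pn_adjuvant","rr_detected","salvage_rt_rr","ned_post_salvage_rr","progression","bsc_bridge","death","alive","attained_age"
0,1,0,0,0,0,0,0,0,0,1,65
1,0,0.95692171171384,0,0,0,0,0,0,0.0430782882861601,0.95692171171384,66
2,0,0.908712500598998,0,0,0,0.00362881855039302,0.0342305698568972,0,0.0534281109937114,0.946571889006289,67
3,0,0.86293204411253,0,0,0,0.00608829332667248,0.0460900706429669,0,0.084889591917831,0.915110408082169,68
4,0,0.819457982877285,0,0,0,0.0077055308526487,0.0494725831078862,0,0.12336390316218,0.87663609683782,69
5,0,0.778174121916999,0,0,0,0.00871824689671177,0.0495883283973088,0,0.163519302788981,0.836480697211019,70
6,0,0.734322812574277,0,0,0,0.0092406104652519,0.0481141362938394,0,0.208322440666631,0.791677559333369,71
7,0,0.692942591998083,0,0,0,0.00945332672778693,0.0461500782583201,0,0.25145400301581,0.74854599698419,72
8,0,0.653894210533534,0,0,0,0.00945130580930249,0.044013830862379,0,0.292640652794784,0.707359347205216,73
9,0,0.617046265458102,0,0,0,0.00930269634202091,0.0418416019547223,0,0.331809436245155,0.668190563754845,74
10,0,0.582274758794892,0,0,0,0.00905631292564511,0.0396963656575726,0,0.36897256262189,0.63102743737811,75
11,0,0.543450235151122,0,0,0,0.00865129535098038,0.0371979403917988,0,0.410700529106099,0.589299470893901,76
12,0,0.507214426909142,0,0,0,0.00821674398593136,0.0348225470567274,0,0.449746282048199,0.550253717951801,77
13,0,0.473394725449385,0,0,0,0.00777070531369093,0.032575228983044,0,0.48625934025388,0.51374065974612,78
14,0,0.441830031233402,0,0,0,0.00732545087371473,0.0304563776537059,0,0.520388140239177,0.479611859760823,79
15,0,0.412369986409114,0,0,0,0.00688916229357847,0.0284636197002219,0,0.552277231597085,0.447722768402915,80
16,0,0.377288015763595,0,0,0,0.0063396608583899,0.0260687350609529,0,0.590303588317062,0.409696411682938,81
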