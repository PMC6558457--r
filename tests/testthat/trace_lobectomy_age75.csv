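"cycle","initial","ned","pn_adjuvant","rr_detected","salvage_rt_rr","ned_post_salvage_rr","progression","bsc_bridge","death","alive","attained_age"
0,1,0,0,0,0,0,0,0,0,1,75
1,0,0.922547200532757,0,0,0,0,0,0,0.0774527994672427,0.922547200532757,76
2,0,0.861034220520181,0,0,0,0.00343842188798681,0.032434562103269,0,0.103092795488563,0.896907204511437,77
3,0,0.803622761500614,0,0,0,0.00566984518582587,0.0429223020521294,0,0.14778509126143,0.85221490873857,78
4,0,0.750039345023613,0,0,0,0.00705277321661696,0.0452816185896159,0,0.197626263170154,0.802373736829846,79
5,0,0.700028727450398,0,0,0,0.00784274766895227,0.0446085952316763,0,0.247519929648973,0.752480070351027,80
6,0,0.640474472589884,0,0,0,0.00805963673305073,0.0419650261972455,0,0.30950086447982,0.69049913552018,81
7,0,0.585986737334799,0,0,0,0.00799420348834761,0.039026802650938,0,0.366992256525915,0.633007743474085,82
8,0,0.536134492517331,0,0,0,0.00774922145213981,0.0360873861444519,0,0.420028899886077,0.579971100113923,83
9,0,0.490523378351802,0,0,0,0.00739521538807352,0.0332621475818257,0,0.468819258678298,0.531180741321702,84
10,0,0.448792584823085,0,0,0,0.00698022029201283,0.0305962679687784,0,0.513630926916124,0.486369073083876,85
11,0,0.395444717975385,0,0,0,0.00629516527716444,0.0270672972354305,0,0.57119281951202,0.42880718048798,86
12,0,0.348438299256383,0,0,0,0.00564461132805258,0.0239218532212511,0,0.621995236194313,0.378004763805687,87
13,0,0.307019522248969,0,0,0,0.00503968064004549,0.021126621615885,0,0.6668141754951,0.3331858245049,88
14,0,0.270524185323919,0,0,0,0.0044852352480658,0.0186478649486231,0,0.706342714479392,0.293657285520608,89
15,0,0.238367040340269,0,0,0,0.00398222295624323,0.0164531585928314,0,0.741197578110656,0.258802421889344,90
16,0,0.199729214050813,0,0,0,0.00335609780244998,0.0138003004269435,0,0.783114387719794,0.216885612280206,91
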