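"cycle","initial","ned","pn_adjuvant","rr_detected","salvage_rt_rr","ned_post_salvage_rr","progression","bsc_bridge","death","alive","attained_age"
0,1,0,0,0,0,0,0,0,0,1,80
1,0,0.89212228531647,0,0,0,0,0,0,0.10787771468353,0.89212228531647,81
2,0,0.816225860122625,0,0,0,0.00325948585561556,0.0307466622342229,0,0.149767991787537,0.850232008212463,82
3,0,0.74678624858764,0,0,0,0.00526884331709208,0.0398866065844139,0,0.208058301510854,0.791941698489146,83
4,0,0.683254143645751,0,0,0,0.00642477832185671,0.0412496407523362,0,0.269071437280056,0.730928562719944,84
5,0,0.625126969989061,0,0,0,0.00700358841634581,0.0398355594265554,0,0.328033882168038,0.671966117831962,85
6,0,0.550818277096934,0,0,0,0.0069314163316683,0.0360905928612955,0,0.406159713710102,0.593840286289898,86
7,0,0.485342640694808,0,0,0,0.00662118710900023,0.0323238910536287,0,0.475712281142563,0.524287718857437,87
8,0,0.42765007747765,0,0,0,0.00618120117368112,0.0287852650706704,0,0.537383456277999,0.462616543722001,88
9,0,0.3768154154039,0,0,0,0.00568093444969237,0.025551666875462,0,0.591951983270945,0.408048016729055,89
10,0,0.332023457410538,0,0,0,0.00516407122848275,0.0226355760286407,0,0.640176895332338,0.359823104667662,90
11,0,0.278204503862513,0,0,0,0.00442879434989714,0.0190424695437476,0,0.698324232243842,0.301675767756158,91
12,0,0.233109270570864,0,0,0,0.0037763105609989,0.0160039977436751,0,0.747110421124462,0.252889578875538,92
13,0,0.195323696315625,0,0,0,0.00320620996232849,0.0134406105333261,0,0.788029483188721,0.211970516811279,93
14,0,0.163662930474489,0,0,0,0.00271349766264694,0.0112816686645958,0,0.822341903198268,0.177658096801732,94
15,0,0.137134179399383,0,0,0,0.00229099994911312,0.00946561403344601,0,0.851109206618058,0.148890793381942,95
16,0,0.10572955085993,0,0,0,0.00177659895664918,0.00730538881258317,0,0.885188461370838,0.114811538629162,96
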