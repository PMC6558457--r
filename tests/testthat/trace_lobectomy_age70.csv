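"cycle","initial","ned","pn_adjuvant","rr_detected","salvage_rt_rr","ned_post_salvage_rr","progression","bsc_bridge","death","alive","attained_age"
0,1,0,0,0,0,0,0,0,0,1,70
1,0,0.94284218713808,0,0,0,0,0,0,0.0571578128619205,0.94284218713808,71
2,0,0.889711578903886,0,0,0,0.00355294097957019,0.0335148183106147,0,0.0732206618059295,0.926779338194071,72
3,0,0.83957496220915,0,0,0,0.00592350078379138,0.0448425453455984,0,0.109658991661461,0.890341008338539,73
4,0,0.792263621023014,0,0,0,0.00744981671151554,0.0478307962743777,0,0.152455765991093,0.847544234008907,74
5,0,0.747618346722604,0,0,0,0.00837591632471985,0.0476411937238487,0,0.196364543228827,0.803635456771173,75
6,0,0.697769154841229,0,0,0,0.00878062460289375,0.0457190756473633,0,0.247731144908514,0.752268855091486,76
7,0,0.651243773754652,0,0,0,0.00888445918007117,0.043372930847501,0,0.296498836217775,0.703501163782225,77
8,0,0.607820580648488,0,0,0,0.00878536327796721,0.0409125999288284,0,0.342481456144716,0.657518543855284,78
9,0,0.567292729924892,0,0,0,0.00855260342530294,0.0384678393275794,0,0.385686827322225,0.614313172677775,79
10,0,0.529467167897282,0,0,0,0.00823497890627597,0.0360962277396838,0,0.426201625456758,0.573798374543242,80
11,0,0.484423269810309,0,0,0,0.00771163302717358,0.0331576780158964,0,0.474707419146621,0.525292580853379,81
12,0,0.443211437010646,0,0,0,0.00717991191959052,0.0304284545205724,0,0.519180196549191,0.480819803450809,82
13,0,0.405505660316364,0,0,0,0.00665631621974849,0.027903647904371,0,0.559934375559516,0.440065624440484,83
14,0,0.371007665455756,0,0,0,0.00615123064288045,0.0255744263014371,0,0.597266677599926,0.402733322400074,84
15,0,0.339444553547149,0,0,0,0.00567085068295338,0.0234299803572322,0,0.631454615412665,0.368545384587335,85
16,0,0.299094860933692,0,0,0,0.0050257625569401,0.0206659749634309,0,0.675213401545936,0.324786598454064,86
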