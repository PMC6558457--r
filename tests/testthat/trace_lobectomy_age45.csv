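"cycle","initial","ned","pn_adjuvant","rr_detected","salvage_rt_rr","ned_post_salvage_rr","progression","bsc_bridge","death","alive","attained_age"
0,1,0,0,0,0,0,0,0,0,1,45
1,0,0.9842421303,0,0,0,0,0,0,0.0157578697,0.9842421303,46
2,0,0.942518767827286,0,0,0,0.00376381923494032,0.0355040285043748,0,0.0182133844333991,0.981786615566601,47
3,0,0.902564115433563,0,0,0,0.00636791172419555,0.0482068595365722,0,0.0428611133056694,0.957138886694331,48
4,0,0.864303195093137,0,0,0,0.00812721954632584,0.0521799928039264,0,0.0753895925566105,0.924610407443389,49
5,0,0.827664207200793,0,0,0,0.00927270735779796,0.0527420320895082,0,0.1103210533519,0.8896789466481,50
6,0,0.791846940161689,0,0,0,0.0099644856415184,0.0518832194103263,0,0.146305354786466,0.853694645213534,51
7,0,0.75757966961511,0,0,0,0.0103351247591089,0.0504549171076878,0,0.181630288518093,0.818369711481907,52
8,0,0.72479531927843,0,0,0,0.0104761016404506,0.0487862074303054,0,0.215942371650814,0.784057628349186,53
9,0,0.693429715603133,0,0,0,0.0104542664625006,0.0470211259155781,0,0.249094892018788,0.750905107981212,54
10,0,0.663421462158651,0,0,0,0.0103184145837484,0.0452285120540628,0,0.281031611203537,0.718968388796463,55
11,0,0.633802842165814,0,0,0,0.0100896369661934,0.043382372143938,0,0.312725148724054,0.687274851275946,56
12,0,0.605506552999335,0,0,0,0.00980905128846139,0.0415707427004107,0,0.343113653011792,0.656886346988208,57
13,0,0.578473558862991,0,0,0,0.00949555902512262,0.0398059117002416,0,0.372224970411645,0.627775029588356,58
14,0,0.552647459628701,0,0,0,0.00916278100130926,0.0380952822351756,0,0.400094477134814,0.599905522865186,59
15,0,0.527974373166456,0,0,0,0.00882047982023962,0.0364431512102426,0,0.426761995803061,0.573238004196939,60
16,0,0.503252889137192,0,0,0,0.00845627878393518,0.034772284534468,0,0.453518547544404,0.546481452455596,61
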