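"cycle","initial","ned","pn_adjuvant","rr_detected","salvage_rt_rr","ned_post_salvage_rr","progression","bsc_bridge","death","alive","attained_age"
0,1,0,0,0,0,0,0,0,0,1,60
1,0,0.967012196869101,0,0,0,0,0,0,0.032987803130899,0.967012196869101,61
2,0,0.921733528441257,0,0,0,0.00368081623651269,0.0347210629478024,0,0.0398645923744278,0.960135407625572,62
3,0,0.878574955107597,0,0,0,0.00619865964261912,0.0469255742932756,0,0.0683008109565079,0.931699189043492,63
4,0,0.837437207093536,0,0,0,0.0078745931716447,0.0505580306632699,0,0.104130169071549,0.895869830928451,64
5,0,0.798225662759457,0,0,0,0.00894289364195872,0.0508660917720641,0,0.14196535182652,0.85803464817348,65
6,0,0.758011474887876,0,0,0,0.00953870511400111,0.0496662595666813,0,0.182783560431441,0.817216439568559,66
7,0,0.719823256590589,0,0,0,0.00982004066338192,0.0479403344626656,0,0.222416368283363,0.777583631716637,67
8,0,0.683558940589025,0,0,0,0.00988007613787916,0.0460105734397069,0,0.260550409833389,0.739449590166611,68
9,0,0.649121601700273,0,0,0,0.00978626966517782,0.0440166146348695,0,0.297075513999679,0.702924486000321,69
10,0,0.616419197781016,0,0,0,0.00958737273797309,0.0420241501179038,0,0.331969279363106,0.668030720636894,70
11,0,0.581683027346438,0,0,0,0.00925993098305873,0.0398148886109819,0,0.369242153059521,0.630757846940479,71
12,0,0.54890429357315,0,0,0,0.0088921091628906,0.0376847435296132,0,0.404518853734346,0.595481146265654,72
13,0,0.517972691892888,0,0,0,0.00850244612552029,0.0356427271752072,0,0.437882134806384,0.562117865193616,73
14,0,0.488784133569562,0,0,0,0.00810394021501805,0.0336930337704229,0,0.469418892444996,0.530581107555004,74
15,0,0.461240395427549,0,0,0,0.00770560429997498,0.0318368737748164,0,0.499217126497659,0.500782873502341,75
16,0,0.430486119431109,0,0,0,0.00723356133089478,0.0297444607991446,0,0.532535858438851,0.467464141561149,76
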