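"cycle","initial","ned","pn_adjuvant","rr_detected","salvage_rt_rr","ned_post_salvage_rr","progression","bsc_bridge","death","alive","attained_age"
0,1,0,0,0,0,0,0,0,0,1,85
1,0,0.84441648,0,0,0,0,0,0,0.15558352,0.84441648,86
2,0,0.744040895682355,0,0,0,0.00297122511545005,0.028027504672,0,0.224960374530195,0.775039625469805,87
3,0,0.655596932982409,0,0,0,0.00462547017380576,0.0350160932840863,0,0.304761503559699,0.695238496440301,88
4,0,0.577666282902054,0,0,0,0.00543191409254139,0.0348750561793908,0,0.382026746826014,0.617973253173986,89
5,0,0.508999230493394,0,0,0,0.00570255529796586,0.0324354412268365,0,0.452862772981803,0.547137227018197,90
6,0,0.426493596236256,0,0,0,0.00536693280020498,0.0279446187240509,0,0.540194852239488,0.459805147760512,91
7,0,0.357361616154535,0,0,0,0.00487523231576469,0.0238003360487577,0,0.613962815480942,0.386037184519058,92
8,0,0.299435503434472,0,0,0,0.00432800362433627,0.0201551006111565,0,0.676081392330036,0.323918607669964,93
9,0,0.250898856127522,0,0,0,0.0037825945990969,0.0170133272927097,0,0.728305221980672,0.271694778019328,94
10,0,0.210229699832087,0,0,0,0.0032697724213295,0.0143323317910745,0,0.772168195955509,0.227831804044491,95
11,0,0.162085716617228,0,0,0,0.00258027564610587,0.0110944009867123,0,0.824239606749954,0.175760393250046,96
12,0,0.124967022034964,0,0,0,0.00202443379420964,0.00857954698148038,0,0.864428997189346,0.135571002810654,97
13,0,0.0963487525132567,0,0,0,0.00158155070784013,0.00662994855375833,0,0.895439748225145,0.104560251774855,98
14,0,0.0742842548353558,0,0,0,0.00123161763804924,0.00512058746363163,0,0.919363540062963,0.0806364599370366,99
15,0,0.0572726721675493,0,0,0,0.000956812441625458,0.0039532158341303,0,0.937817299556695,0.0621827004433049,100
16,0,0.0382243300212684,0,0,0,0.000642292568937186,0.00264111206975428,0,0.95849226534004,0.0415077346599597,101
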