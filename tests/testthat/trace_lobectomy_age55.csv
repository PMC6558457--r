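"cycle","initial","ned","pn_adjuvant","rr_detected","salvage_rt_rr","ned_post_salvage_rr","progression","bsc_bridge","death","alive","attained_age"
0,1,0,0,0,0,0,0,0,0,1,55
1,0,0.974433324059706,0,0,0,0,0,0,0.0255666759402939,0.974433324059706,56
2,0,0.930929500351965,0,0,0,0.00371753908717941,0.035067468833805,0,0.03028549172705,0.96971450827295,57
3,0,0.889367915923675,0,0,0,0.00627480783037027,0.0475020372139119,0,0.0568552390320423,0.943144760967958,58
4,0,0.849661859007981,0,0,0,0.00798954407145642,0.051296061313333,0,0.0910525356072296,0.90894746439277,59
5,0,0.811728489106923,0,0,0,0.00909417209055404,0.0517265451954708,0,0.127450793607052,0.872549206392948,60
6,0,0.773720710889951,0,0,0,0.00973638783353014,0.0506955566403024,0,0.165847344636216,0.834152655363784,61
7,0,0.737492580947466,0,0,0,0.0100610907851866,0.0491171140563261,0,0.203329214211021,0.796670785788979,62
8,0,0.702960770336565,0,0,0,0.010160507778426,0.047316516876998,0,0.239562205008011,0.760437794991989,63
9,0,0.670045851847528,0,0,0,0.0101017272835136,0.0454354776843241,0,0.274416943184634,0.725583056815366,64
10,0,0.63867211731193,0,0,0,0.00993347979437075,0.0435412346511162,0,0.307853168242583,0.692146831757417,65
11,0,0.606496152904654,0,0,0,0.00965493619954447,0.0415132909774692,0,0.342335619918331,0.657664380081669,66
12,0,0.575941196613242,0,0,0,0.00933010007692406,0.0395409482793855,0,0.375187755030448,0.624812244969552,67
13,0,0.546925582903805,0,0,0,0.0089777036050194,0.0376350329692914,0,0.406461680521884,0.593538319478117,68
14,0,0.519371760508978,0,0,0,0.00861107676674292,0.0358015104509168,0,0.436215652273362,0.563784347726638,69
15,0,0.493206085153341,0,0,0,0.00823963158519229,0.0340432885620157,0,0.46451099469945,0.53548900530055,70
16,0,0.46541316323441,0,0,0,0.00782044881008204,0.0321577467062726,0,0.494608641249234,0.505391358750766,71
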