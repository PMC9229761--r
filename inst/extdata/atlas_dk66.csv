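index,hemisphere,name,abbreviation,network_label
0,left,caudalanteriorcingulate,l CaudACC,salience
1,left,caudalmiddlefrontal,l CaudMFG,other
2,left,cuneus,l CUN,other
3,left,entorhinal,l EC,other
4,left,fusiform,l FuG,other
5,left,inferiorparietal,l IPL,default mode
6,left,inferiortemporal,l ITG,other
7,left,isthmuscingulate,l IstCC,default mode
8,left,lateraloccipital,l LOcC,other
9,left,lateralorbitofrontal,l LatOFC,other
10,left,lingual,l LING,other
11,left,medialorbitofrontal,l MedOFC,default mode
12,left,middletemporal,l MTG,language
13,left,parahippocampal,l PaHC,default mode
14,left,paracentral,l ParaC,other
15,left,parsopercularis,l IFGoper,language
16,left,parsorbitalis,l IFGorb,other
17,left,parstriangularis,l IFGtri,language
18,left,pericalcarine,l PeriCal,other
19,left,postcentral,l PoCG,other
20,left,posteriorcingulate,l PCC,default mode
21,left,precentral,l PreCG,other
22,left,precuneus,l PCUN,default mode
23,left,rostralanteriorcingulate,l RostACC,salience
24,left,rostralmiddlefrontal,l RostMFG,other
25,left,superiorfrontal,l SFG,default mode
26,left,superiorparietal,l SPL,other
27,left,superiortemporal,l STG,language
28,left,supramarginal,l SMG,language
29,left,frontalpole,l FP,other
30,left,temporalpole,l TP,other
31,left,transversetemporal,l TranTG,other
32,left,insula,l INS,salience
33,right,caudalanteriorcingulate,r CaudACC,salience
34,right,caudalmiddlefrontal,r CaudMFG,other
35,right,cuneus,r CUN,other
36,right,entorhinal,r EC,other
37,right,fusiform,r FuG,other
38,right,inferiorparietal,r IPL,default mode
39,right,inferiortemporal,r ITG,other
40,right,isthmuscingulate,r IstCC,default mode
41,right,lateraloccipital,r LOcC,other
42,right,lateralorbitofrontal,r LatOFC,other
43,right,lingual,r LING,other
44,right,medialorbitofrontal,r MedOFC,default mode
45,right,middletemporal,r MTG,language
46,right,parahippocampal,r PaHC,default mode
47,right,paracentral,r ParaC,other
48,right,parsopercularis,r IFGoper,language
49,right,parsorbitalis,r IFGorb,other
50,right,parstriangularis,r IFGtri,language
51,right,pericalcarine,r PeriCal,other
52,right,postcentral,r PoCG,other
53,right,posteriorcingulate,r PCC,default mode
54,right,precentral,r PreCG,other
55,right,precuneus,r PCUN,default mode
56,right,rostralanteriorcingulate,r RostACC,salience
57,right,rostralmiddlefrontal,r RostMFG,other
58,right,superiorfrontal,r SFG,default mode
59,right,superiorparietal,r SPL,other
60,right,superiortemporal,r STG,language
61,right,supramarginal,r SMG,language
62,right,frontalpole,r FP,other
63,right,temporalpole,r TP,other
64,right,transversetemporal,r TranTG,other
65,right,insula,r INS,salience
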