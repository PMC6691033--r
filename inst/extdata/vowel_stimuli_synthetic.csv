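item,F1,F2
1,295,2240
2,330,1990
3,365,1740
4,400,1490
5,435,1240
6,470,990
7,505,860
8,540,1110
9,575,1360
10,610,1610
11,645,1860
12,680,1540
13,715,1290
14,750,1040
15,785,1170
16,760,1420
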