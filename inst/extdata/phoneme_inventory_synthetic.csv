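phoneme,F1,F2,grapheme
i,294,2208,ie
y,305,1730,uu
u,339,810,oe
I,388,2003,i
Y,438,1498,u
e:,407,2017,ee
2:,443,1497,eu
o:,487,911,oo
E,610,1781,e
O,520,850,o
A,680,1058,a
a:,795,1301,aa
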