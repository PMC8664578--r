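epoch,stage,artifact
0,W,0
1,N3,0
2,W,0
3,N1,0
4,REM,0
5,N2,0
6,N1,0
7,N2,0
8,N2,0
9,W,0
10,REM,0
11,REM,0
12,N1,0
13,N1,0
14,W,0
15,REM,0
16,REM,0
17,W,0
18,W,1
19,REM,0
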