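landmark,x,y
1,60,300
2,250,180
3,265,182
4,265,310
5,300,345
6,285,430
7,450,150
8,435,310
9,435,475
10,650,460
11,650,315
12,650,175
13,800,428
14,720,318
15,800,195
16,880,395
17,850,312
18,880,248
19,955,312
20,1020,315
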