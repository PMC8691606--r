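id,variety,starch_percent
1,L7xMIN-021 10#,14.71
2,V7,12.09
3,Burbank,18.34
4,Shapoti,14.73
5,Favorita,12.50
6,HMxYSP-4 6#,13.58
7,Jizhangshu 12#,14.90
8,Qingshu 9#,18.83
9,HMxMIN-021 5#,13.78
10,Huasong 7#,14.20
11,Houqihong,18.87
12,Hongmei,14.32
13,Longshu 3#,21.47
14,Longshu 6#,20.05
15,Longshu 7#,18.75
16,HMxMIN-021 9#,18.42
17,Heimeiren,13.65
18,Zicai 1#,14.89
19,Zicai 2#,14.87
20,Zaicai 3#,14.94
21,Neinongshu 1#,18.71
22,Neinongshu 2#,19.43
23,Neinongshu 3#,18.26
24,Neinongshu 4#,20.30
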