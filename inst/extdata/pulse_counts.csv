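id,lower,upper
1,44,68
2,62,72
3,56,90
4,70,112
5,54,72
6,70,100
7,63,75
8,72,100
9,76,98
10,86,96
11,86,100
12,67,88
13,89,100
14,56,65
15,87,93
16,43,70
17,86,112
18,65,77
19,89,99
20,90,101
21,77,89
22,98,115
23,54,66
24,75,89
25,85,100
26,67,78
27,76,97
28,95,117
29,86,99
30,66,100
31,77,88
32,88,99
33,83,112
34,56,65
35,45,78
36,87,97
37,67,89
38,84,102
39,90,109
40,91,108
41,56,77
42,77,99
43,73,89
44,89,114
45,64,70
46,56,74
47,91,117
48,67,88
49,54,77
50,92,100
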