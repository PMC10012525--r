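family,score,selected
1,1.631,FALSE
2,3.299,TRUE
3,2.698,TRUE
4,1.822,FALSE
5,1.101,FALSE
6,0.667,FALSE
7,1.497,FALSE
8,2.915,TRUE
9,2.191,FALSE
10,2.173,FALSE
11,2.337,FALSE
12,1.697,FALSE
13,1.430,FALSE
14,2.717,TRUE
15,2.327,FALSE
16,2.301,FALSE
17,2.022,FALSE
18,1.226,FALSE
19,2.423,FALSE
20,2.418,FALSE
21,1.455,FALSE
22,1.787,FALSE
23,2.662,TRUE
24,1.461,FALSE
25,2.673,TRUE
26,1.985,FALSE
27,2.242,FALSE
28,1.078,FALSE
29,1.226,FALSE
30,1.540,FALSE
31,3.156,TRUE
32,1.789,FALSE
33,2.488,FALSE
34,1.511,FALSE
35,1.873,FALSE
36,1.724,FALSE
37,1.366,FALSE
38,0.607,FALSE
39,2.762,TRUE
40,2.077,FALSE
41,2.806,TRUE
42,1.811,FALSE
43,1.616,FALSE
44,1.714,FALSE
45,1.880,FALSE
46,0.915,FALSE
47,0.846,FALSE
48,2.320,FALSE
49,1.869,FALSE
50,1.833,FALSE
51,2.369,FALSE
52,1.409,FALSE
53,1.195,FALSE
54,2.456,FALSE
55,1.499,FALSE
56,2.960,TRUE
57,1.780,FALSE
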