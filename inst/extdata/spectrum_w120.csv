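# Relative fluence of a 120 kVp tungsten-anode beam, simplified model:
# Kramers' bremsstrahlung continuum hardened by 2.5 mm Al inherent
# filtration, sampled at 1 keV (characteristic lines omitted).
# Normalised to unit sum.
energy_kev,fluence
10,0
11,2.3e-07
12,4.27e-06
13,3.425e-05
14,0.00015644
15,0.00048415
16,0.00112806
17,0.00216028
18,0.003579
19,0.00531777
20,0.00727176
21,0.00917753
22,0.01106672
23,0.01286916
24,0.01453482
25,0.01603229
26,0.01734545
27,0.01846997
28,0.01940986
29,0.0201747
30,0.02077748
31,0.02105392
32,0.0212277
33,0.02131116
34,0.02131577
35,0.02125199
36,0.02112929
37,0.02095613
38,0.02074004
39,0.02048769
40,0.02020494
41,0.01981955
42,0.01942567
43,0.01902566
44,0.01862152
45,0.018215
46,0.01780757
47,0.01740049
48,0.01699483
49,0.0165915
50,0.01619127
51,0.01576447
52,0.01534601
53,0.01493589
54,0.01453404
55,0.01414041
56,0.0137549
57,0.01337741
58,0.01300781
59,0.01264598
60,0.01229177
61,0.01192938
62,0.01157612
63,0.01123166
64,0.0108957
65,0.01056795
66,0.01024811
67,0.00993593
68,0.00963113
69,0.00933348
70,0.00904274
71,0.00875867
72,0.00848106
73,0.00820971
74,0.0079444
75,0.00768494
76,0.00743116
77,0.00718287
78,0.0069399
79,0.00670209
80,0.00646927
81,0.00623762
82,0.00601107
83,0.00578944
84,0.00557257
85,0.00536031
86,0.00515253
87,0.00494906
88,0.00474979
89,0.00455457
90,0.00436329
91,0.00417584
92,0.00399208
93,0.00381192
94,0.00363525
95,0.00346197
96,0.00329198
97,0.00312519
98,0.00296151
99,0.00280085
100,0.00264312
101,0.00248759
102,0.00233493
103,0.00218507
104,0.00203793
105,0.00189343
106,0.0017515
107,0.00161207
108,0.00147508
109,0.00134047
110,0.00120816
111,0.00107811
112,0.00095025
113,0.00082452
114,0.00070088
115,0.00057927
116,0.00045965
117,0.00034195
118,0.00022614
119,0.00011217
120,0
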