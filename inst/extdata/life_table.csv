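age,q_annual
18,0.000588901106536754
19,0.000598263600854354
20,0.000608610655265518
21,0.000620045794270552
22,0.000632683425136338
23,0.000646649981339231
24,0.000662085186020622
25,0.000679143448021891
26,0.000697995404376428
27,0.000718829624579809
28,0.000741854493555127
29,0.000767300291985906
30,0.000795421494625193
31,0.000826499309328432
32,0.000860844481904488
33,0.000898800394475985
34,0.000940746487886668
35,0.000987102041838939
36,0.00103833034989431
37,0.00109494333026861
38,0.00115750661752734
39,0.00122664518486726
40,0.00130304955170268
41,0.00138748263678623
42,0.0014807873231395
43,0.00158389480767818
44,0.00169783381565014
45,0.00182374076789471
46,0.00196287099754233
47,0.00211661112214223
48,0.0022864926873859
49,0.00247420720963842
50,0.00268162275642614
51,0.00291080221692097
52,0.00316402342831057
53,0.00344380133879618
54,0.00375291240379527
55,0.00409442142874283
56,0.00447171108962841
57,0.00488851438099214
58,0.00534895026040216
59,0.00585756277826144
60,0.00641936400186871
61,0.0070398810626302
62,0.00772520767470852
63,0.00848206049155598
64,0.00931784068294084
65,0.0102407011281509
66,0.0112596196298063
67,0.0123844785554447
68,0.0136261513087621
69,0.0149965960165721
70,0.0165089567880849
71,0.0181776728562545
72,0.020018595842083
73,0.0220491152863582
74,0.0242882924627116
75,0.0267570023130883
76,0.0294780831223804
77,0.0324764932618979
78,0.0357794739686209
79,0.039416716673794
80,0.0434205328331704
81,0.0478260235227869
82,0.0526712452269178
83,0.0579973672354525
84,0.0638488148613625
85,0.0702733912599476
86,0.0773223689554191
87,0.0850505402356543
88,0.0935162133469403
89,0.1027811389016
90,0.112910348113194
91,0.12397188142991
92,0.136036382914073
93,0.149176532426816
94,0.163466284495076
95,0.178979879915692
96,0.195790594039791
97,0.213969184753985
98,0.233582004050537
99,0.254688740538325
100,0.277339767244709
101,0.301573080720195
102,0.327410835046182
103,0.354855499191926
104,0.383885699543622
105,0.414451852345907
106,0.446471743704683
107,0.479826277179035
108,0.514355678823082
109,0.549856522699265
110,1
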