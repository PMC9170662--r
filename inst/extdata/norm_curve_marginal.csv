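age,norm
18,0.9724
19,0.9694
20,0.9664
21,0.9634
22,0.9604
23,0.9574
24,0.9544
25,0.9514
26,0.9484
27,0.9454
28,0.9424
29,0.9394
30,0.9364
31,0.9334
32,0.9304
33,0.9274
34,0.9244
35,0.9214
36,0.9184
37,0.9154
38,0.9124
39,0.9094
40,0.9064
41,0.9034
42,0.9004
43,0.8974
44,0.8944
45,0.8914
46,0.8884
47,0.8854
48,0.8824
49,0.8794
50,0.8764
51,0.8734
52,0.8704
53,0.8674
54,0.8644
55,0.8614
56,0.8584
57,0.8554
58,0.8524
59,0.8494
60,0.8464
61,0.8434
62,0.8404
63,0.8374
64,0.8344
65,0.8314
66,0.8284
67,0.8254
68,0.8224
69,0.8194
70,0.8164
71,0.8134
72,0.8104
73,0.8074
74,0.8044
75,0.8014
76,0.7984
77,0.7954
78,0.7924
79,0.7894
80,0.7864
81,0.7834
82,0.7804
83,0.7774
84,0.7744
85,0.7714
86,0.7684
87,0.7654
88,0.7624
89,0.7594
90,0.7564
91,0.7534
92,0.7504
93,0.7474
94,0.7444
95,0.7414
96,0.7384
97,0.7354
98,0.7324
99,0.7294
100,0.7264
101,0.7234
102,0.7204
103,0.7174
104,0.7144
105,0.7114
106,0.7084
107,0.7054
108,0.7024
109,0.6994
110,0.6964
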