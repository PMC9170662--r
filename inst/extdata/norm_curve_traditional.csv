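age,norm
18,0.9534
19,0.9504
20,0.9474
21,0.9444
22,0.9414
23,0.9384
24,0.9354
25,0.9324
26,0.9294
27,0.9264
28,0.9234
29,0.9204
30,0.9174
31,0.9144
32,0.9114
33,0.9084
34,0.9054
35,0.9024
36,0.8994
37,0.8964
38,0.8934
39,0.8904
40,0.8874
41,0.8844
42,0.8814
43,0.8784
44,0.8754
45,0.8724
46,0.8694
47,0.8664
48,0.8634
49,0.8604
50,0.8574
51,0.8544
52,0.8514
53,0.8484
54,0.8454
55,0.8424
56,0.8394
57,0.8364
58,0.8334
59,0.8304
60,0.8274
61,0.8244
62,0.8214
63,0.8184
64,0.8154
65,0.8124
66,0.8094
67,0.8064
68,0.8034
69,0.8004
70,0.7974
71,0.7944
72,0.7914
73,0.7884
74,0.7854
75,0.7824
76,0.7794
77,0.7764
78,0.7734
79,0.7704
80,0.7674
81,0.7644
82,0.7614
83,0.7584
84,0.7554
85,0.7524
86,0.7494
87,0.7464
88,0.7434
89,0.7404
90,0.7374
91,0.7344
92,0.7314
93,0.7284
94,0.7254
95,0.7224
96,0.7194
97,0.7164
98,0.7134
99,0.7104
100,0.7074
101,0.7044
102,0.7014
103,0.6984
104,0.6954
105,0.6924
106,0.6894
107,0.6864
108,0.6834
109,0.6804
110,0.6774
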