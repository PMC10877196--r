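"age","qx"
35,0.0021
36,0.00226
37,0.002433
38,0.002619
39,0.002818
40,0.003034
41,0.003265
42,0.003515
43,0.003783
44,0.004072
45,0.004382
46,0.004717
47,0.005077
48,0.005465
49,0.005882
50,0.006331
51,0.006814
52,0.007334
53,0.007894
54,0.008497
55,0.009145
56,0.009844
57,0.010595
58,0.011404
59,0.012274
60,0.013212
61,0.01422
62,0.015306
63,0.016474
64,0.017732
65,0.019085
66,0.020542
67,0.02211
68,0.023798
69,0.025615
70,0.027571
71,0.029675
72,0.031941
73,0.034379
74,0.037004
75,0.039828
76,0.042869
77,0.046141
78,0.049664
79,0.053455
80,0.057536
81,0.061928
82,0.066656
83,0.071744
84,0.077221
85,0.083116
86,0.089461
87,0.096291
88,0.103641
89,0.111553
90,0.120069
91,0.129235
92,0.139101
93,0.14972
94,0.16115
95,0.173452
96,0.186693
97,0.200945
98,0.216285
99,0.232796
100,0.250568
101,0.269696
102,0.290285
103,0.312445
104,0.336297
105,0.36197
106,0.389602
107,0.419344
108,0.451357
109,0.485813
110,0.5229
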