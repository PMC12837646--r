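sample_id,response,mean,sd
1,TPC,11.184,0.103
1,TFC,0.804,0.034
1,DPPH,16.634,0.521
1,ABTS,21.335,0.432
1,CUPRAC,31.314,0.276
1,FRAP,17.485,0.044
1,MC,16.389,0.61
1,PM,0.532,0.028
1,AChE,1.973,0.077
1,BChE,1.755,0.201
1,Tyrosinase,52.258,1.345
1,alpha-amylase,0.833,0.01
1,alpha-glucosidase,1.07,0.066
2,TPC,10.793,0.159
2,TFC,1.001,0.025
2,DPPH,17.709,0.509
2,ABTS,22.707,0.071
2,CUPRAC,33.1,0.11
2,FRAP,21.161,0.217
2,MC,17.456,0.502
2,PM,0.441,0.012
2,AChE,1.926,0.046
2,BChE,2.094,0.152
2,Tyrosinase,54.097,0.383
2,alpha-amylase,0.739,0.026
2,alpha-glucosidase,0.826,0.019
3,TPC,13.301,0.473
3,TFC,1.648,0.063
3,DPPH,27.054,0.144
3,ABTS,34.898,0.937
3,CUPRAC,43.283,0.53
3,FRAP,28.328,0.131
3,MC,14.004,0.586
3,PM,0.591,0.014
3,AChE,2.54,0.02
3,BChE,1.789,0.089
3,Tyrosinase,54.72,0.516
3,alpha-amylase,0.863,0.008
3,alpha-glucosidase,1.114,0.1
4,TPC,10.589,0.07
4,TFC,0.858,0.048
4,DPPH,17.635,0.593
4,ABTS,22.765,0.497
4,CUPRAC,31.747,0.894
4,FRAP,17.776,0.045
4,MC,15.74,0.253
4,PM,0.522,0.02
4,AChE,1.948,0.058
4,BChE,2.141,0.045
4,Tyrosinase,53.661,0.405
4,alpha-amylase,0.785,0.022
4,alpha-glucosidase,1.09,0.042
5,TPC,9.372,0.358
5,TFC,1.023,0.046
5,DPPH,15.53,0.576
5,ABTS,15.503,0.28
5,CUPRAC,29.701,0.261
5,FRAP,19.31,0.12
5,MC,18.501,1.477
5,PM,0.44,0.05
5,AChE,2.213,0.06
5,BChE,2.078,0.103
5,Tyrosinase,52.503,0.733
5,alpha-amylase,0.862,0.021
5,alpha-glucosidase,0.924,0.015
6,TPC,16.494,0.149
6,TFC,2.103,0.006
6,DPPH,32.695,0.568
6,ABTS,46.764,0.315
6,CUPRAC,57.285,1.619
6,FRAP,38.9,1.298
6,MC,19.14,0.148
6,PM,0.542,0.032
6,AChE,2.32,0.019
6,BChE,2.058,0.016
6,Tyrosinase,55.453,0.201
6,alpha-amylase,0.738,0.019
6,alpha-glucosidase,0.965,0.085
7,TPC,8.692,0.507
7,TFC,0.88,0.049
7,DPPH,16.261,0.428
7,ABTS,15.38,0.649
7,CUPRAC,30.01,0.354
7,FRAP,17.596,0.432
7,MC,12.929,0.577
7,PM,0.536,0.022
7,AChE,2.242,0.028
7,BChE,2.36,0.044
7,Tyrosinase,54.47,0.892
7,alpha-amylase,0.852,0.012
7,alpha-glucosidase,0.864,0.119
8,TPC,10.97,0.191
8,TFC,1.139,0.02
8,DPPH,22.457,0.368
8,ABTS,32.279,0.265
8,CUPRAC,32.648,0.859
8,FRAP,22.445,0.473
8,MC,17.188,0.293
8,PM,0.394,0.021
8,AChE,1.579,0.085
8,BChE,1.545,0.056
8,Tyrosinase,52.718,0.571
8,alpha-amylase,0.827,0.06
8,alpha-glucosidase,0.742,0.086
9,TPC,14.955,0.328
9,TFC,1.563,0.042
9,DPPH,23.886,0.708
9,ABTS,32.856,0.768
9,CUPRAC,43.669,0.903
9,FRAP,28.556,0.313
9,MC,17.971,0.005
9,PM,0.594,0.005
9,AChE,1.996,0.048
9,BChE,2.16,0.134
9,Tyrosinase,54.086,0.42
9,alpha-amylase,0.816,0.033
9,alpha-glucosidase,0.706,0.086
10,TPC,15.213,0.316
10,TFC,1.617,0.026
10,DPPH,26.829,0.206
10,ABTS,38.387,0.758
10,CUPRAC,42.129,0.608
10,FRAP,28.546,0.434
10,MC,18.001,0.452
10,PM,0.517,0.001
10,AChE,1.817,0.03
10,BChE,1.388,0.014
10,Tyrosinase,53.475,0.772
10,alpha-amylase,0.827,0.008
10,alpha-glucosidase,0.988,0.125
11,TPC,12.236,0.224
11,TFC,1.765,0.043
11,DPPH,22.619,0.579
11,ABTS,26.854,0.155
11,CUPRAC,42.861,0.406
11,FRAP,26.13,0.41
11,MC,20.374,0.283
11,PM,0.58,0.019
11,AChE,2.194,0.025
11,BChE,1.904,0.097
11,Tyrosinase,52.305,0.475
11,alpha-amylase,0.902,0.019
11,alpha-glucosidase,1.123,0.018
12,TPC,11.475,0.026
12,TFC,1.263,0.075
12,DPPH,21.935,0.581
12,ABTS,29.346,1.007
12,CUPRAC,35.25,0.255
12,FRAP,22.747,0.262
12,MC,17.474,0.827
12,PM,0.482,0.034
12,AChE,1.881,0.032
12,BChE,1.498,0.139
12,Tyrosinase,50.553,0.615
12,alpha-amylase,0.844,0.008
12,alpha-glucosidase,1.016,0.082
13,TPC,9.982,0.425
13,TFC,1.18,0.037
13,DPPH,19.428,0.589
13,ABTS,23.197,0.167
13,CUPRAC,29.87,0.108
13,FRAP,19.527,0.6
13,MC,18.489,0.9
13,PM,0.424,0.06
13,AChE,1.74,0.087
13,BChE,1.451,0.08
13,Tyrosinase,51.374,0.663
13,alpha-amylase,0.895,0.009
13,alpha-glucosidase,1.019,0.153
14,TPC,9.174,0.071
14,TFC,0.952,0.05
14,DPPH,17.98,0.471
14,ABTS,16.036,0.397
14,CUPRAC,30.639,0.252
14,FRAP,19.027,0.488
14,MC,18.109,0.44
14,PM,0.461,0.049
14,AChE,2.357,0.07
14,BChE,1.994,0.075
14,Tyrosinase,52.666,0.559
14,alpha-amylase,0.889,0.012
14,alpha-glucosidase,0.929,0.082
15,TPC,14.176,0.286
15,TFC,1.295,0.026
15,DPPH,21.1,0.818
15,ABTS,22.209,0.203
15,CUPRAC,41.53,0.451
15,FRAP,24.499,0.212
15,MC,8.611,0.503
15,PM,0.74,0.035
15,AChE,2.17,0.02
15,BChE,1.847,0.138
15,Tyrosinase,43.139,1.983
15,alpha-amylase,0.766,0.021
15,alpha-glucosidase,0.902,0.063
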