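"study_id","effect","se"
1,0.2694,0.1201
2,0.3642,0.1929
3,0.3729,0.0626
4,0.468,0.2831
5,0.4018,0.1763
6,0.2387,0.053
7,0.608,0.3959
8,0.1942,0.1269
9,0.6239,0.2284
10,0.5296,0.3226
11,0.2796,0.0506
12,0.467,0.2089
13,0.325,0.0586
14,0.3363,0.0807
15,0.267,0.1428
16,0.1847,0.12
17,0.3071,0.0527
18,0.323,0.1377
19,0.2831,0.0581
20,0.6327,0.2886
21,0.4224,0.2356
22,0.6601,0.2673
23,0.3403,0.091
24,0.2342,0.0673
25,1.3926,0.5143
26,0.4357,0.1973
27,0.4321,0.1682
28,0.8527,0.3663
29,0.6465,0.408
30,0.2446,0.0729
31,0.9219,0.5289
32,0.6636,0.1506
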