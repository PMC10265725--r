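"fibre_id","node_i","node_j","mean_fa"
1,49,54,0.5066
2,65,57,0.6993
3,25,27,0.2964
4,74,80,0.5128
5,18,89,0.4601
6,49,28,0.3991
7,47,15,0.4688
8,24,23,0.2247
9,71,61,0.346
10,89,83,0.2619
11,37,10,0.4179
12,20,13,0.5946
13,26,62,0.455
14,3,1,0.2433
15,41,11,0.6123
16,89,26,0.7117
17,27,74,0.7203
18,36,79,0.2534
19,5,81,0.2078
20,84,8,0.454
21,34,70,0.784
22,3,74,0.4994
23,58,84,0.7968
24,42,25,0.4969
26,30,80,0.5362
27,43,16,0.3436
28,15,3,0.6352
29,22,56,0.6716
30,58,21,0.4699
31,8,67,0.4814
32,36,10,0.4411
33,68,85,0.7414
34,86,7,0.5382
35,18,19,0.6146
36,69,29,0.3994
37,4,45,0.2569
38,50,42,0.7627
39,88,46,0.6026
40,87,24,0.209
41,49,30,0.2679
42,26,45,0.7087
43,6,42,0.4681
44,6,39,0.4411
45,2,52,0.4593
46,3,85,0.5982
47,21,53,0.3094
48,2,43,0.703
49,58,43,0.7504
50,10,26,0.679
51,40,62,0.5018
52,5,6,0.3527
53,33,58,0.6003
54,49,23,0.7647
55,73,42,0.7885
56,29,41,0.2314
57,76,60,0.4294
58,84,45,0.6837
59,9,82,0.5287
60,35,85,0.3827
61,16,33,0.4414
62,69,11,0.2166
63,2,45,0.7094
64,82,14,0.2186
65,24,2,0.5914
66,18,45,0.5581
67,69,35,0.3876
68,55,28,0.7921
69,40,45,0.6974
70,21,16,0.5646
71,57,80,0.2829
72,42,45,0.7226
73,18,8,0.5463
74,13,72,0.6795
75,53,37,0.2169
76,54,87,0.3538
77,83,10,0.6541
78,32,60,0.698
79,80,75,0.5142
80,60,23,0.5828
81,29,33,0.4927
82,81,86,0.5491
83,73,15,0.2602
84,85,68,0.705
85,43,60,0.4415
86,58,10,0.6636
88,29,45,0.3593
89,55,84,0.6976
90,38,55,0.5922
91,1,48,0.6791
92,13,8,0.3117
93,78,3,0.6528
94,5,48,0.6416
95,73,75,0.6511
96,55,13,0.3996
97,16,18,0.2345
98,90,85,0.6046
99,43,5,0.2249
100,42,31,0.5861
101,42,56,0.3798
102,57,20,0.4361
103,29,82,0.7541
104,25,67,0.6075
105,63,8,0.6305
106,32,19,0.6303
107,81,10,0.3369
108,14,79,0.4453
109,6,61,0.5427
110,47,12,0.7277
111,43,35,0.5568
112,62,52,0.7509
113,37,32,0.4108
114,80,61,0.3524
115,31,54,0.6285
117,6,1,0.466
118,86,77,0.6177
119,38,7,0.6041
120,6,75,0.3083
121,84,11,0.639
122,15,77,0.3959
123,34,63,0.4115
124,42,15,0.6734
125,87,37,0.4187
126,60,14,0.3699
127,12,90,0.3564
128,26,49,0.2162
129,41,28,0.5938
130,65,82,0.6481
131,66,59,0.5787
132,56,17,0.2327
133,24,50,0.5164
134,25,39,0.2527
135,61,34,0.3622
136,62,76,0.2008
137,14,35,0.6239
138,34,20,0.6782
139,66,90,0.2806
140,32,89,0.5595
141,27,8,0.4155
142,10,20,0.6068
143,57,28,0.4196
144,28,55,0.6805
145,37,56,0.7922
146,10,46,0.49
147,5,85,0.2472
148,35,56,0.2807
149,78,62,0.7366
150,14,69,0.6281
151,28,42,0.7245
152,54,12,0.7423
153,90,3,0.4864
154,31,18,0.2401
155,43,50,0.6319
156,52,47,0.3632
157,81,65,0.3959
158,59,8,0.431
159,27,30,0.3984
160,30,20,0.2591
161,52,51,0.5487
162,84,34,0.6537
163,75,64,0.5102
164,81,21,0.3647
165,73,52,0.4668
166,17,83,0.7374
167,62,82,0.7528
168,13,40,0.5128
169,63,24,0.6595
170,49,42,0.66
171,61,29,0.7029
172,1,34,0.7644
173,17,22,0.4537
174,33,4,0.5628
175,28,87,0.3321
176,2,17,0.7155
177,31,20,0.7566
178,8,51,0.5501
179,80,39,0.5953
180,3,9,0.2392
181,13,63,0.3467
182,12,62,0.5054
183,65,19,0.509
184,30,21,0.6582
185,51,63,0.3607
186,60,81,0.6126
187,37,7,0.5346
188,47,49,0.4586
189,56,68,0.7165
190,70,45,0.267
191,16,65,0.3898
192,10,81,0.6446
193,71,36,0.528
194,73,57,0.3078
195,25,34,0.609
196,3,27,0.2632
197,82,26,0.3731
198,53,57,0.6344
199,28,85,0.2272
200,79,35,0.2653
201,57,58,0.4506
202,84,13,0.5579
203,89,41,0.3183
204,80,43,0.5007
205,88,10,0.6948
206,61,27,0.2552
207,43,65,0.4822
208,22,78,0.7286
209,26,58,0.4614
210,54,28,0.366
211,54,32,0.2343
212,84,30,0.731
213,55,37,0.2887
214,54,24,0.3904
215,58,44,0.6084
216,45,34,0.3696
217,37,88,0.4548
218,43,28,0.4925
219,79,48,0.3448
220,85,18,0.4161
221,34,30,0.2415
222,25,22,0.4164
223,65,26,0.7898
224,14,49,0.314
225,49,84,0.7231
226,11,30,0.2676
227,28,72,0.3165
228,18,51,0.6381
229,55,47,0.3621
230,42,89,0.326
231,36,58,0.5495
232,20,38,0.2506
233,79,65,0.4831
234,61,30,0.3835
235,71,47,0.7344
236,27,4,0.327
237,5,28,0.5126
238,86,41,0.2085
239,20,70,0.5161
240,41,20,0.4313
241,11,14,0.2009
242,38,9,0.5398
243,73,31,0.4687
244,23,24,0.5695
245,90,70,0.2301
246,11,22,0.5916
247,19,11,0.3938
248,85,59,0.2951
249,36,73,0.3271
250,42,82,0.4234
251,86,19,0.6042
252,89,33,0.294
253,54,40,0.4423
254,59,75,0.3575
255,30,55,0.4098
256,59,38,0.2679
257,85,34,0.376
258,21,1,0.2793
259,70,57,0.4749
260,47,55,0.6414
261,74,18,0.2323
262,88,60,0.4356
263,55,68,0.7049
264,7,79,0.4387
265,14,71,0.4738
266,12,14,0.7749
267,53,10,0.6655
268,51,71,0.486
269,10,69,0.7907
270,89,88,0.3774
271,37,38,0.3088
272,66,5,0.6635
273,35,21,0.7224
274,34,63,0.3878
275,27,35,0.7486
276,46,3,0.7491
277,31,73,0.6845
278,80,64,0.4117
279,53,45,0.6053
280,24,29,0.3613
281,38,42,0.7746
282,85,17,0.2728
284,75,64,0.5773
285,78,49,0.3452
286,33,90,0.7572
287,36,76,0.5557
288,45,88,0.4166
289,22,88,0.565
290,44,30,0.5619
291,64,86,0.7286
292,7,51,0.5783
293,5,74,0.7195
294,31,33,0.7535
295,32,7,0.5413
296,82,25,0.648
297,39,24,0.4352
298,13,66,0.2849
299,30,36,0.7671
300,54,52,0.3458
301,2,8,0.2133
302,28,78,0.3367
303,3,17,0.3419
304,33,58,0.5338
305,84,37,0.5976
306,9,17,0.4991
307,54,80,0.2693
308,10,52,0.5861
309,71,25,0.5763
310,82,67,0.3533
311,25,14,0.3415
312,74,73,0.412
313,73,56,0.3843
314,19,44,0.6625
315,79,55,0.337
316,46,73,0.4762
317,3,88,0.7028
318,22,67,0.3539
319,61,36,0.4762
320,20,35,0.7006
321,42,39,0.3982
322,87,60,0.5032
323,17,37,0.663
324,82,86,0.3078
325,83,4,0.7957
326,46,29,0.7738
327,17,8,0.5104
328,74,44,0.2728
329,37,44,0.5378
330,45,12,0.2225
331,50,9,0.7724
332,51,88,0.2073
333,74,67,0.546
334,48,3,0.6455
335,34,26,0.3132
336,58,7,0.3782
337,68,27,0.4682
338,89,87,0.4349
339,90,44,0.5942
340,61,49,0.5684
341,33,79,0.6373
342,86,47,0.3923
343,19,20,0.2865
344,70,45,0.2323
345,89,19,0.7731
346,30,66,0.2154
347,89,22,0.7525
348,2,37,0.42
349,38,50,0.619
350,9,33,0.5416
351,56,68,0.3704
352,75,82,0.2068
353,6,62,0.4528
354,31,42,0.5686
355,69,56,0.2029
356,14,25,0.5982
357,64,39,0.2694
358,47,14,0.7414
359,65,61,0.2606
360,41,74,0.5392
361,10,23,0.3509
362,49,74,0.5487
363,76,21,0.7715
364,22,41,0.6364
365,1,39,0.4427
366,4,70,0.4954
367,67,52,0.6033
368,59,28,0.4809
369,53,8,0.3774
370,38,31,0.5277
371,59,90,0.641
372,69,62,0.663
373,42,24,0.6886
374,62,37,0.3999
375,20,58,0.7347
376,34,83,0.3852
377,87,84,0.6193
378,57,11,0.3161
379,20,71,0.786
380,9,56,0.3015
381,27,44,0.3023
382,46,4,0.5769
383,46,31,0.6405
384,3,52,0.7635
385,63,35,0.661
386,18,61,0.2998
387,10,61,0.3682
388,40,65,0.4552
389,84,48,0.7024
390,53,5,0.2909
391,70,17,0.5995
392,29,43,0.6909
393,68,65,0.6042
394,9,88,0.4253
395,40,33,0.7306
396,87,82,0.5426
397,90,67,0.482
398,76,69,0.5817
399,74,39,0.6444
400,87,70,0.2875
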