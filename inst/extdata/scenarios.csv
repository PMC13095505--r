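scenario,stage,dose,piT,piE,utility
1,1,1,0.01,0.02,40.8
1,1,2,0.02,0.03,41
1,1,3,0.03,0.12,46
1,1,4,0.04,0.19,49.8
1,1,5,0.06,0.41,62.2
1,1,6,0.08,0.56,70.4
1,2,1,0.01,0.06,43.2
1,2,2,0.02,0.11,45.8
1,2,3,0.03,0.15,47.8
1,2,4,0.05,0.21,50.6
1,2,5,0.08,0.58,71.6
1,2,6,0.28,0.58,63.6
2,1,1,0.01,0.01,40.2
2,1,2,0.02,0.02,40.4
2,1,3,0.03,0.12,46
2,1,4,0.05,0.26,53.6
2,1,5,0.06,0.52,68.8
2,1,6,0.07,0.31,55.8
2,2,1,0.02,0.01,39.8
2,2,2,0.07,0.07,41.4
2,2,3,0.14,0.21,47
2,2,4,0.17,0.56,66.8
2,2,5,0.26,0.39,53
2,2,6,0.49,0.16,30
3,1,1,0.01,0.01,40.2
3,1,2,0.02,0.02,40.4
3,1,3,0.03,0.12,46
3,1,4,0.05,0.42,63.2
3,1,5,0.21,0.62,68.8
3,1,6,0.42,0.63,61
3,2,1,0.02,0.02,40.4
3,2,2,0.03,0.05,41.8
3,2,3,0.06,0.13,45.4
3,2,4,0.08,0.65,75.8
3,2,5,0.29,0.65,67.4
3,2,6,0.52,0.65,58.2
4,1,1,0.01,0.01,40.2
4,1,2,0.04,0.05,41.4
4,1,3,0.07,0.21,49.8
4,1,4,0.11,0.58,70.4
4,1,5,0.57,0.59,52.6
4,1,6,0.65,0.59,49.4
4,2,1,0.02,0.04,41.6
4,2,2,0.05,0.08,42.8
4,2,3,0.21,0.61,68.2
4,2,4,0.55,0.62,55.2
4,2,5,0.62,0.65,54.2
4,2,6,0.66,0.68,54.4
5,1,1,0.01,0.01,40.2
5,1,2,0.04,0.05,41.4
5,1,3,0.07,0.21,49.8
5,1,4,0.11,0.58,70.4
5,1,5,0.57,0.59,52.6
5,1,6,0.65,0.59,49.4
5,2,1,0.02,0.04,41.6
5,2,2,0.05,0.65,77
5,2,3,0.21,0.49,61
5,2,4,0.55,0.42,43.2
5,2,5,0.62,0.38,38
5,2,6,0.66,0.36,35.2
6,1,1,0.02,0.01,39.8
6,1,2,0.18,0.12,40
6,1,3,0.22,0.42,56.4
6,1,4,0.55,0.44,44.4
6,1,5,0.61,0.45,42.6
6,1,6,0.62,0.46,42.8
6,2,1,0.02,0.01,39.8
6,2,2,0.18,0.02,34
6,2,3,0.22,0.03,33
6,2,4,0.55,0.05,21
6,2,5,0.61,0.06,19.2
6,2,6,0.62,0.07,19.4
7,1,1,0.01,0.01,40.2
7,1,2,0.02,0.02,40.4
7,1,3,0.03,0.12,46
7,1,4,0.05,0.26,53.6
7,1,5,0.06,0.52,68.8
7,1,6,0.07,0.31,55.8
7,2,1,0.01,0.01,40.2
7,2,2,0.02,0.02,40.4
7,2,3,0.03,0.12,46
7,2,4,0.05,0.26,53.6
7,2,5,0.06,0.52,68.8
7,2,6,0.07,0.31,55.8
8,1,1,0.02,0.1,45.2
8,1,2,0.06,0.25,52.6
8,1,3,0.09,0.55,69.4
8,1,4,0.45,0.56,55.6
8,1,5,0.52,0.57,53.4
8,1,6,0.55,0.61,54.6
8,2,1,0.02,0.1,45.2
8,2,2,0.06,0.25,52.6
8,2,3,0.09,0.55,69.4
8,2,4,0.45,0.56,55.6
8,2,5,0.52,0.57,53.4
8,2,6,0.55,0.61,54.6
9,1,1,0.02,0.42,64.4
9,1,2,0.33,0.43,52.6
9,1,3,0.47,0.44,47.6
9,1,4,0.51,0.45,46.6
9,1,5,0.52,0.46,46.8
9,1,6,0.54,0.47,46.6
9,2,1,0.02,0.42,64.4
9,2,2,0.33,0.43,52.6
9,2,3,0.47,0.44,47.6
9,2,4,0.51,0.45,46.6
9,2,5,0.52,0.46,46.8
9,2,6,0.54,0.47,46.6
10,1,1,0.51,0.11,26.2
10,1,2,0.52,0.21,31.8
10,1,3,0.54,0.55,51.4
10,1,4,0.57,0.58,52
10,1,5,0.58,0.61,53.4
10,1,6,0.59,0.62,53.6
10,2,1,0.51,0.11,26.2
10,2,2,0.52,0.21,31.8
10,2,3,0.54,0.55,51.4
10,2,4,0.57,0.58,52
10,2,5,0.58,0.61,53.4
10,2,6,0.59,0.62,53.6
11,1,1,0.01,0.02,40.8
11,1,2,0.02,0.03,41
11,1,3,0.03,0.12,46
11,1,4,0.04,0.19,49.8
11,1,5,0.06,0.41,62.2
11,1,6,0.08,0.56,70.4
11,2,1,0.01,0.06,43.2
11,2,2,0.02,0.11,45.8
11,2,3,0.03,0.15,47.8
11,2,4,0.05,0.21,50.6
11,2,5,0.08,0.58,71.6
11,2,6,0.28,0.58,63.6
11,3,1,0.02,0.07,43.4
11,3,2,0.03,0.12,46
11,3,3,0.04,0.16,48
11,3,4,0.06,0.61,74.2
11,3,5,0.42,0.42,48.4
11,3,6,0.46,0.31,40.2
12,1,1,0.01,0.05,42.6
12,1,2,0.03,0.15,47.8
12,1,3,0.06,0.25,52.6
12,1,4,0.08,0.6,72.8
12,1,5,0.11,0.45,62.6
12,1,6,0.51,0.4,43.6
12,2,1,0.02,0.08,44
12,2,2,0.06,0.18,48.4
12,2,3,0.08,0.29,54.2
12,2,4,0.12,0.46,62.8
12,2,5,0.52,0.31,37.8
12,2,6,0.56,0.24,32
12,3,1,0.01,0.1,45.6
12,3,2,0.04,0.25,53.4
12,3,3,0.07,0.68,78
12,3,4,0.33,0.68,67.6
12,3,5,0.51,0.68,60.4
12,3,6,0.58,0.68,57.6
13,1,1,0.02,0.1,45.2
13,1,2,0.05,0.25,53
13,1,3,0.12,0.4,59.2
13,1,4,0.24,0.55,63.4
13,1,5,0.48,0.55,53.8
13,1,6,0.54,0.55,51.4
13,2,1,0.03,0.12,46
13,2,2,0.07,0.44,63.6
13,2,3,0.14,0.55,67.4
13,2,4,0.26,0.56,63.2
13,2,5,0.58,0.58,51.6
13,2,6,0.6,0.61,52.6
13,3,1,0.05,0.02,39.2
13,3,2,0.15,0.68,74.8
13,3,3,0.33,0.69,68.2
13,3,4,0.54,0.7,60.4
13,3,5,0.62,0.71,57.8
13,3,6,0.65,0.71,56.6
14,1,1,0.02,0.18,50
14,1,2,0.08,0.35,57.8
14,1,3,0.55,0.45,45
14,1,4,0.58,0.5,46.8
14,1,5,0.61,0.55,48.6
14,1,6,0.62,0.6,51.2
14,2,1,0.04,0.15,47.4
14,2,2,0.24,0.25,45.4
14,2,3,0.28,0.4,52.8
14,2,4,0.52,0.45,46.2
14,2,5,0.58,0.5,46.8
14,2,6,0.61,0.55,48.6
14,3,1,0.06,0.45,64.6
14,3,2,0.52,0.46,46.8
14,3,3,0.58,0.47,45
14,3,4,0.68,0.49,42.2
14,3,5,0.78,0.5,38.8
14,3,6,0.88,0.51,35.4
15,1,1,0.02,0.18,50
15,1,2,0.08,0.35,57.8
15,1,3,0.55,0.45,45
15,1,4,0.58,0.5,46.8
15,1,5,0.61,0.55,48.6
15,1,6,0.62,0.6,51.2
15,2,1,0.04,0.15,47.4
15,2,2,0.24,0.25,45.4
15,2,3,0.28,0.4,52.8
15,2,4,0.52,0.45,46.2
15,2,5,0.58,0.5,46.8
15,2,6,0.61,0.55,48.6
15,3,1,0.06,0.01,38.2
15,3,2,0.52,0.05,22.2
15,3,3,0.58,0.25,31.8
15,3,4,0.68,0.35,33.8
15,3,5,0.78,0.45,35.8
15,3,6,0.88,0.5,34.8
16,1,1,0.02,0.02,40.4
16,1,2,0.03,0.11,45.4
16,1,3,0.05,0.22,51.2
16,1,4,0.06,0.59,73
16,1,5,0.25,0.59,65.4
16,1,6,0.59,0.59,51.8
16,2,1,0.02,0.02,40.4
16,2,2,0.03,0.11,45.4
16,2,3,0.05,0.22,51.2
16,2,4,0.06,0.59,73
16,2,5,0.25,0.59,65.4
16,2,6,0.59,0.59,51.8
16,3,1,0.02,0.02,40.4
16,3,2,0.03,0.11,45.4
16,3,3,0.05,0.22,51.2
16,3,4,0.06,0.59,73
16,3,5,0.25,0.59,65.4
16,3,6,0.59,0.59,51.8
17,1,1,0.01,0.07,43.8
17,1,2,0.05,0.56,71.6
17,1,3,0.26,0.56,63.2
17,1,4,0.48,0.56,54.4
17,1,5,0.55,0.58,52.8
17,1,6,0.59,0.61,53
17,2,1,0.01,0.07,43.8
17,2,2,0.05,0.56,71.6
17,2,3,0.26,0.56,63.2
17,2,4,0.48,0.56,54.4
17,2,5,0.55,0.58,52.8
17,2,6,0.59,0.61,53
17,3,1,0.01,0.07,43.8
17,3,2,0.05,0.56,71.6
17,3,3,0.26,0.56,63.2
17,3,4,0.48,0.56,54.4
17,3,5,0.55,0.58,52.8
17,3,6,0.59,0.61,53
18,1,1,0.52,0.05,22.2
18,1,2,0.53,0.17,29
18,1,3,0.54,0.25,33.4
18,1,4,0.55,0.36,39.6
18,1,5,0.57,0.48,46
18,1,6,0.58,0.52,48
18,2,1,0.52,0.05,22.2
18,2,2,0.53,0.17,29
18,2,3,0.54,0.25,33.4
18,2,4,0.55,0.36,39.6
18,2,5,0.57,0.48,46
18,2,6,0.58,0.52,48
18,3,1,0.52,0.05,22.2
18,3,2,0.53,0.17,29
18,3,3,0.54,0.25,33.4
18,3,4,0.55,0.36,39.6
18,3,5,0.57,0.48,46
18,3,6,0.58,0.52,48
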