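generation,population,births,deaths,n_objects,n_dies_out,n_still_life,n_oscillator,n_spaceship,n_unresolved
0,378,0,0,22,13,0,0,0,9
1,388,176,166,21,12,0,2,0,7
2,329,144,203,33,21,1,0,0,11
3,291,141,179,29,11,2,1,0,15
4,318,156,129,23,9,0,1,0,13
5,268,134,184,41,26,1,0,0,14
6,271,139,136,28,15,0,2,0,11
7,242,114,143,28,16,1,0,0,11
8,264,126,104,20,10,1,0,0,9
9,248,116,132,33,21,0,0,0,12
10,216,109,141,38,24,1,3,0,10
11,216,107,107,24,9,1,1,0,13
12,209,85,92,21,6,2,3,0,10
13,215,88,82,20,7,1,0,0,12
14,204,81,92,29,13,2,1,0,13
15,217,90,77,27,11,2,1,0,13
16,213,95,99,22,10,1,2,0,9
17,206,88,95,24,11,1,1,0,11
18,200,81,87,27,11,2,4,0,10
19,205,99,94,17,10,1,1,0,5
20,211,90,84,18,12,1,1,0,4
21,185,90,116,24,10,1,0,0,13
22,195,85,75,18,4,1,2,0,11
23,187,70,78,28,11,2,1,0,14
24,177,76,86,30,15,2,1,0,12
25,171,78,84,25,9,2,1,0,13
26,180,78,69,17,4,3,1,0,9
27,193,76,63,21,6,2,2,0,11
28,198,87,82,21,5,2,2,0,12
29,193,81,86,22,9,1,1,0,11
30,171,67,89,32,23,1,1,0,7
31,175,83,79,16,3,1,1,0,11
32,159,70,86,27,13,2,3,0,9
33,152,70,77,22,10,1,1,0,10
34,159,76,69,22,11,2,1,0,8
35,137,61,83,31,23,2,0,0,6
36,132,64,69,18,10,1,1,0,6
37,121,45,56,18,11,1,2,0,4
38,127,53,47,14,3,1,2,0,8
39,108,46,65,16,5,1,0,0,10
40,135,57,30,13,2,3,1,0,7
41,110,41,66,24,15,1,2,0,6
42,115,61,56,14,5,1,1,0,7
43,109,44,50,16,8,2,0,0,6
44,104,40,45,14,5,1,2,0,6
45,107,51,48,14,4,0,0,0,10
46,100,44,51,15,4,1,1,0,9
47,105,45,40,16,6,2,0,0,8
48,108,45,42,15,3,2,1,0,9
49,111,45,42,15,8,2,0,0,5
50,104,39,46,13,5,2,1,0,5
51,113,41,32,12,7,1,0,0,4
52,95,37,55,13,6,1,1,0,5
53,91,41,45,14,6,1,0,0,7
54,90,40,41,11,7,0,0,0,4
55,95,43,38,10,5,0,0,0,5
56,81,36,50,11,5,0,0,0,6
57,70,27,38,15,8,1,0,0,6
58,80,32,22,10,3,1,0,0,6
59,72,29,37,9,2,1,1,0,5
60,79,31,24,9,4,1,0,0,4
61,65,22,36,13,5,1,1,0,6
62,76,31,20,9,2,1,0,0,6
63,68,19,27,12,4,2,0,0,6
64,72,18,14,11,4,1,0,0,6
65,79,32,25,10,2,1,0,0,7
66,77,24,26,10,3,2,1,0,4
67,91,30,16,10,2,2,0,0,6
68,101,38,28,11,6,2,0,0,3
69,81,25,45,12,4,2,1,0,5
70,90,33,24,12,5,2,0,0,5
71,87,32,35,13,7,2,2,0,2
72,95,31,23,13,6,2,0,1,4
73,93,35,37,18,5,3,4,1,5
74,94,40,39,11,3,2,0,1,5
75,87,29,36,16,7,2,0,1,6
76,94,35,28,15,3,3,0,1,8
77,111,44,27,11,3,1,0,0,7
78,97,37,51,12,5,1,2,0,4
79,108,40,29,11,4,1,2,0,4
80,102,39,45,13,4,0,2,0,7
81,115,46,33,14,5,0,2,0,7
82,110,44,49,14,7,0,1,0,6
83,127,58,41,11,7,0,0,0,4
84,102,47,72,17,13,0,0,0,4
85,107,48,43,13,5,0,0,0,8
86,95,40,52,19,11,0,2,0,6
87,100,44,39,15,9,1,0,0,5
88,108,53,45,6,2,0,0,0,4
89,114,42,36,10,6,0,0,0,4
90,111,50,53,8,2,0,1,0,5
91,109,42,44,15,10,0,0,0,5
92,108,52,53,14,8,0,0,0,6
93,107,48,49,12,7,0,0,0,5
94,126,57,38,8,4,0,0,0,4
95,119,49,56,18,12,0,0,0,6
96,112,49,56,14,4,1,0,0,9
97,106,39,45,11,4,2,0,0,5
98,123,44,27,10,3,1,1,0,5
99,106,41,58,19,12,1,0,0,6
100,113,44,37,17,7,2,0,0,8
101,118,52,47,17,7,1,2,0,7
102,107,48,59,17,9,2,0,0,6
103,96,39,50,16,9,1,0,0,6
104,85,32,43,18,13,2,1,0,2
105,75,29,39,12,7,2,0,0,3
106,75,20,20,14,7,3,2,0,2
107,65,24,34,13,10,2,0,0,1
108,55,20,30,14,8,2,1,0,3
109,53,18,20,10,6,2,0,0,2
110,51,14,16,10,6,1,0,0,3
111,47,14,18,10,7,1,0,0,2
112,46,15,16,7,3,1,0,0,3
113,47,17,16,10,7,1,0,0,2
114,38,15,24,10,6,2,1,0,1
115,36,11,13,7,2,2,1,0,2
116,37,11,10,6,2,1,0,0,3
117,40,12,9,8,2,2,1,0,3
118,42,8,6,7,2,1,0,0,4
119,43,7,6,6,1,1,1,0,3
120,41,5,7,7,3,1,0,0,3
121,42,9,8,7,1,1,1,0,4
122,49,10,3,6,2,1,0,0,3
123,41,6,14,8,3,1,1,0,3
124,47,11,5,6,2,1,0,0,3
125,42,10,15,7,2,1,1,0,3
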