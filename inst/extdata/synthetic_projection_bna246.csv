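"atlas_roi","database_region"
1,1
2,1
3,1
4,1
5,1
6,1
7,1
8,1
9,2
10,2
11,2
12,2
13,2
14,2
15,2
16,2
17,3
18,3
19,3
20,3
21,3
22,3
23,3
24,3
25,4
26,4
27,4
28,4
29,4
30,4
31,4
32,4
33,5
34,5
35,5
36,5
37,5
38,5
39,5
40,6
41,6
42,6
43,6
44,6
45,6
46,6
47,7
48,7
49,7
50,7
51,7
52,7
53,7
54,8
55,8
56,8
57,8
58,8
59,8
60,8
61,9
62,9
63,9
64,9
65,9
66,9
67,9
68,10
69,10
70,10
71,10
72,10
73,10
74,10
75,11
76,11
77,11
78,11
79,11
80,11
81,11
82,12
83,12
84,12
85,12
86,12
87,12
88,12
89,13
90,13
91,13
92,13
93,13
94,13
95,13
96,14
97,14
98,14
99,14
100,14
101,14
102,14
103,15
104,15
105,15
106,15
107,15
108,15
109,15
110,16
111,16
112,16
113,16
114,16
115,16
116,16
117,17
118,17
119,17
120,17
121,17
122,17
123,17
124,18
125,18
126,18
127,18
128,18
129,18
130,18
131,18
132,19
133,19
134,19
135,19
136,19
137,19
138,19
139,19
140,20
141,20
142,20
143,20
144,20
145,20
146,20
147,20
148,21
149,21
150,21
151,21
152,21
153,21
154,21
155,21
156,22
157,22
158,22
159,22
160,22
161,22
162,22
163,23
164,23
165,23
166,23
167,23
168,23
169,23
170,24
171,24
172,24
173,24
174,24
175,24
176,24
177,25
178,25
179,25
180,25
181,25
182,25
183,25
184,26
185,26
186,26
187,26
188,26
189,26
190,26
191,27
192,27
193,27
194,27
195,27
196,27
197,27
198,28
199,28
200,28
201,28
202,28
203,28
204,28
205,29
206,29
207,29
208,29
209,29
210,29
211,29
212,30
213,30
214,30
215,30
216,30
217,30
218,30
219,31
220,31
221,31
222,31
223,31
224,31
225,31
226,32
227,32
228,32
229,32
230,32
231,32
232,32
233,33
234,33
235,33
236,33
237,33
238,33
239,33
240,34
241,34
242,34
243,34
244,34
245,34
246,34
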