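node_id,label,network,x,y,z
1,default_1,default,-23,-51,5
2,occipital_3,occipital,-58,-99,19
3,occipital_6,occipital,13,-91,4
4,default_23,default,-29,-47,20
5,cinguloopercular_23,cinguloopercular,-50,44,30
6,sensorimotor_29,sensorimotor,30,-28,68
7,cerebellum_16,cerebellum,-37,-52,-45
8,cinguloopercular_20,cinguloopercular,6,35,23
9,sensorimotor_26,sensorimotor,15,-8,61
10,frontoparietal_5,frontoparietal,-23,-10,21
11,cinguloopercular_18,cinguloopercular,53,8,35
12,frontoparietal_14,frontoparietal,38,50,26
13,sensorimotor_10,sensorimotor,-51,-21,37
14,occipital_5,occipital,-24,-92,7
15,sensorimotor_19,sensorimotor,-44,-31,69
16,frontoparietal_7,frontoparietal,8,-1,40
17,cerebellum_5,cerebellum,-14,-73,-24
18,cinguloopercular_24,cinguloopercular,-25,41,-4
19,sensorimotor_2,sensorimotor,33,-43,64
20,sensorimotor_30,sensorimotor,23,-45,59
21,cerebellum_8,cerebellum,-7,-73,-30
22,cinguloopercular_31,cinguloopercular,-13,-16,7
23,cinguloopercular_30,cinguloopercular,58,-5,42
24,default_7,default,-46,-61,-10
25,default_13,default,-54,-44,5
26,sensorimotor_31,sensorimotor,-30,-5,68
27,occipital_7,occipital,28,-94,-1
28,cerebellum_14,cerebellum,57,-76,-42
29,default_33,default,10,-1,19
30,occipital_17,occipital,53,-88,22
31,sensorimotor_16,sensorimotor,22,-26,34
32,frontoparietal_19,frontoparietal,-23,-39,30
33,cinguloopercular_29,cinguloopercular,38,22,15
34,default_21,default,17,-11,23
35,cerebellum_18,cerebellum,-45,-62,-41
36,cinguloopercular_22,cinguloopercular,-11,-2,13
37,cinguloopercular_14,cinguloopercular,4,28,39
38,sensorimotor_6,sensorimotor,21,-22,35
39,sensorimotor_32,sensorimotor,-38,-11,57
40,cinguloopercular_13,cinguloopercular,32,-5,40
41,cerebellum_15,cerebellum,56,-54,-23
42,sensorimotor_8,sensorimotor,-54,-17,43
43,sensorimotor_27,sensorimotor,-26,-19,41
44,occipital_15,occipital,8,-88,-2
45,default_3,default,21,53,23
46,cinguloopercular_9,cinguloopercular,43,32,31
47,frontoparietal_4,frontoparietal,-40,17,30
48,sensorimotor_23,sensorimotor,-22,-29,63
49,default_29,default,54,22,44
50,cinguloopercular_6,cinguloopercular,-32,-6,33
51,cerebellum_9,cerebellum,28,-78,-35
52,occipital_2,occipital,-35,-67,15
53,frontoparietal_8,frontoparietal,-19,-54,40
54,frontoparietal_20,frontoparietal,2,-32,37
55,default_24,default,-49,17,27
56,cinguloopercular_2,cinguloopercular,-9,4,21
57,default_31,default,59,-25,3
58,cerebellum_11,cerebellum,28,-60,-50
59,default_10,default,-35,54,-12
60,default_20,default,17,45,37
61,sensorimotor_9,sensorimotor,10,-19,52
62,default_30,default,-34,38,-4
63,occipital_1,occipital,-34,-85,5
64,sensorimotor_4,sensorimotor,-48,-31,48
65,cerebellum_4,cerebellum,-48,-73,-52
66,cinguloopercular_5,cinguloopercular,30,40,19
67,occipital_16,occipital,-20,-70,-9
68,cerebellum_1,cerebellum,-51,-61,-38
69,occipital_10,occipital,58,-67,-8
70,frontoparietal_13,frontoparietal,15,17,42
71,default_16,default,-2,-35,13
72,occipital_22,occipital,-49,-69,-4
73,cinguloopercular_19,cinguloopercular,15,37,15
74,frontoparietal_15,frontoparietal,24,-41,41
75,occipital_9,occipital,36,-78,0
76,sensorimotor_22,sensorimotor,4,-42,40
77,default_32,default,18,-29,3
78,cinguloopercular_8,cinguloopercular,-29,39,39
79,default_27,default,16,-50,18
80,cinguloopercular_7,cinguloopercular,-43,-4,20
81,cinguloopercular_21,cinguloopercular,27,31,40
82,occipital_18,occipital,15,-84,6
83,cerebellum_6,cerebellum,-9,-53,-27
84,occipital_14,occipital,20,-93,-7
85,default_22,default,-7,-27,5
86,sensorimotor_18,sensorimotor,18,-39,47
87,cinguloopercular_16,cinguloopercular,45,-17,35
88,sensorimotor_5,sensorimotor,19,-16,41
89,frontoparietal_6,frontoparietal,54,-58,57
90,sensorimotor_17,sensorimotor,9,-34,48
91,cinguloopercular_28,cinguloopercular,20,5,13
92,sensorimotor_12,sensorimotor,56,-24,35
93,default_14,default,33,50,1
94,cerebellum_3,cerebellum,-2,-57,-29
95,sensorimotor_13,sensorimotor,1,-38,67
96,frontoparietal_12,frontoparietal,5,-49,39
97,frontoparietal_1,frontoparietal,17,4,53
98,occipital_11,occipital,24,-93,-6
99,cinguloopercular_26,cinguloopercular,56,-14,19
100,sensorimotor_3,sensorimotor,-5,-36,58
101,sensorimotor_28,sensorimotor,10,-43,39
102,cinguloopercular_3,cinguloopercular,48,-5,41
103,frontoparietal_18,frontoparietal,37,32,24
104,default_12,default,-43,40,42
105,default_25,default,7,24,23
106,frontoparietal_3,frontoparietal,-11,-25,26
107,default_8,default,-53,-19,-7
108,default_15,default,-15,17,16
109,sensorimotor_1,sensorimotor,-48,-42,65
110,frontoparietal_16,frontoparietal,-52,45,50
111,cerebellum_7,cerebellum,6,-64,-47
112,cerebellum_12,cerebellum,56,-55,-22
113,occipital_12,occipital,-20,-75,17
114,frontoparietal_11,frontoparietal,25,-14,58
115,frontoparietal_17,frontoparietal,-17,-28,48
116,frontoparietal_9,frontoparietal,-12,18,46
117,sensorimotor_15,sensorimotor,-34,-25,62
118,sensorimotor_14,sensorimotor,25,-13,37
119,sensorimotor_21,sensorimotor,-26,-32,63
120,default_9,default,-13,-43,31
121,cerebellum_17,cerebellum,52,-78,-33
122,frontoparietal_10,frontoparietal,36,-43,58
123,default_34,default,30,-69,14
124,default_28,default,11,-27,36
125,cinguloopercular_15,cinguloopercular,24,44,26
126,cerebellum_10,cerebellum,51,-64,-20
127,frontoparietal_21,frontoparietal,-10,45,29
128,cinguloopercular_25,cinguloopercular,-13,32,34
129,occipital_21,occipital,-32,-79,15
130,occipital_20,occipital,16,-92,22
131,cinguloopercular_17,cinguloopercular,-3,20,30
132,cinguloopercular_32,cinguloopercular,-11,-8,16
133,sensorimotor_25,sensorimotor,48,-17,58
134,default_17,default,56,52,15
135,sensorimotor_20,sensorimotor,8,-37,42
136,sensorimotor_7,sensorimotor,-8,-11,56
137,cerebellum_2,cerebellum,-6,-77,-52
138,sensorimotor_24,sensorimotor,2,-10,36
139,default_11,default,-41,51,-8
140,cinguloopercular_4,cinguloopercular,-7,-2,13
141,default_6,default,-48,19,38
142,occipital_8,occipital,-43,-82,11
143,default_26,default,20,25,14
144,default_19,default,5,2,-12
145,occipital_19,occipital,-40,-94,-2
146,default_5,default,-51,22,3
147,cinguloopercular_1,cinguloopercular,5,32,25
148,frontoparietal_2,frontoparietal,-53,-40,29
149,cerebellum_13,cerebellum,-14,-79,-45
150,sensorimotor_33,sensorimotor,18,-19,67
151,cinguloopercular_27,cinguloopercular,3,5,31
152,default_4,default,13,54,22
153,cinguloopercular_10,cinguloopercular,-41,28,32
154,sensorimotor_11,sensorimotor,-6,-21,37
155,default_18,default,-51,-64,-13
156,occipital_4,occipital,-2,-79,21
157,occipital_13,occipital,3,-83,20
158,cinguloopercular_11,cinguloopercular,-28,23,6
159,default_2,default,3,46,13
160,cinguloopercular_12,cinguloopercular,-13,0,21
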