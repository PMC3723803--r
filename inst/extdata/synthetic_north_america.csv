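aoa,gjt
24,166
28,158
23,200
20,140
57,123
63,127
23,178
65,134
7,201
33,142
7,172
27,158
53,145
36,133
17,160
28,148
41,126
70,93
54,92
10,175
21,167
48,104
36,142
53,110
42,121
68,109
7,199
6,201
44,136
38,112
41,138
23,172
24,160
52,134
20,189
35,142
46,140
21,167
49,129
68,114
6,185
43,129
41,126
29,157
48,156
58,93
25,176
71,117
16,130
28,130
30,136
49,119
26,159
20,157
56,124
45,155
17,204
48,120
43,182
5,196
26,184
6,178
40,132
54,132
15,138
23,171
23,135
7,204
15,165
8,174
47,105
21,158
53,124
25,151
57,94
57,109
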