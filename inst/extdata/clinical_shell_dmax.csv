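patient,shell_1cm_cgy,shell_3cm_cgy,shell_5cm_cgy
1,427,156,112
2,374,140,106
3,430,157,117
4,423,173,138
5,458,171,133
6,426,155,120
7,428,168,129
8,370,146,98
9,390,123,88
10,344,108,74
11,423,170,105
12,417,174,137
13,368,135,107
14,475,181,124
15,357,119,84
16,536,210,162
17,396,165,123
18,471,198,167
19,522,181,134
20,486,200,149
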