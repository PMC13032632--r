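"age_start","q_annual","disability_weight"
0,0.00459422355936056,0.045
5,0.000580322975919229,0.05
10,0.000483602479932691,0.055
15,0.000725403719899037,0.075
20,0.000967204959865382,0.09
25,0.00120900619983173,0.095
30,0.00145080743979807,0.1
35,0.00216435037021247,0.105
40,0.00322883133663198,0.11
45,0.00481685033250567,0.12
50,0.00718589629087352,0.13
55,0.0107200975614139,0.145
60,0.0159925063032412,0.16
65,0.023858015880359,0.18
70,0.0355919773270371,0.2
75,0.0530969908143621,0.22
80,0.0792114022672971,0.245
85,0.118169526237152,0.27
90,0.176288217749151,0.295
95,0.262991117141345,0.32
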