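"age","qx"
56,0.00403504556463091
57,0.00443717358598369
58,0.00487937722555861
59,0.00536565037358616
60,0.0059003849468247
61,0.00648841055542854
62,0.00713503812297067
63,0.00784610785358703
64,0.00862804197947143
65,0.00948790276512551
66,0.0104334562922457
67,0.0114732426013391
68,0.0126166528235726
69,0.0138740139994934
70,0.0152566823506864
71,0.0167771458467785
72,0.0184491369941521
73,0.0202877568650539
74,0.0223096114873019
75,0.0245329618264346
76,0.0269778887149094
77,0.0296664742179567
78,0.0326230010741463
79,0.0358741720119734
80,0.0394493509232835
81,0.0433808280717658
82,0.0477041117318203
83,0.0524582488918212
84,0.0576861779183003
85,0.0634351163662388
86,0.0697569874380893
87,0.0767088889432152
88,0.0843536089932914
89,0.0927601930913178
90,0.102004567736075
91,0.112170226174285
92,0.12334898249405
93,0.135641800870377
94,0.149159707452362
95,0.164024793128008
96,0.180371316223441
97,0.198346915095858
98,0.218113941572106
99,0.239850927276223
100,0.263754196089506
101,0.290039637306492
102,0.318944655501647
103,0.35073031471753
104,0.385683696340297
105,0.424120491958375
106,0.466387854622466
107,0.51286753425886
108,0.563979325554446
109,0.620184859453993
110,1
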