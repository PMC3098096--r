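ID MZF1
P0      A      C      G      T
01      3      5      4      8
02      0      0     19      1
03      2      0     18      0
04      0      0     19      1
05      0      0     20      0
06     18      0      2      0
XX
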