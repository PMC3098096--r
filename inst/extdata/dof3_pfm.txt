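>Dof3
A [21 21 21  0  0  6]
C [ 0  0  0  0 10  6]
G [ 0  0  0 21  3  9]
T [ 0  0  0  0  8  0]
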