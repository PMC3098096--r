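>site1
GGAGGA
>site2
AGAGGA
>site3
TTGGGA
>site4
TGGTGA
>site5
AGGGGG
>site6
CGGGGG
>site7
TGGGGA
>site8
TGGGGA
>site9
TGGGGA
>site10
TGGGGA
>site11
TGGGGA
>site12
TGGGGA
>site13
AGGGGA
>site14
CGGGGA
>site15
CGGGGA
>site16
CGGGGA
>site17
CGGGGA
>site18
GGGGGA
>site19
GGGGGA
>site20
GGGGGA
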