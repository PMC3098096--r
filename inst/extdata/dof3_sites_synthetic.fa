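>site1
AAAGCA
>site2
AAAGCA
>site3
AAAGCA
>site4
AAAGCC
>site5
AAAGCC
>site6
AAAGCC
>site7
AAAGCG
>site8
AAAGCG
>site9
AAAGCG
>site10
AAAGCG
>site11
AAAGGA
>site12
AAAGGC
>site13
AAAGGG
>site14
AAAGTA
>site15
AAAGTA
>site16
AAAGTC
>site17
AAAGTC
>site18
AAAGTG
>site19
AAAGTG
>site20
AAAGTG
>site21
AAAGTG
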