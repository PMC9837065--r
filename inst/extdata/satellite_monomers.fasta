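>HS2/HS3|attcc_pentamer
ATTCC
>MaSat|ga5tga_nonamer
GAAAAATGA
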