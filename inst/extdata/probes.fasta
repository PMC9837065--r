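>HS2/HS3|DYZ1_probe
TCCATTCCATTCCATTCCATTCCATTCCATTCCATTCCATTCCATTCC
>MaSat|MaSat_probe
AGGACCTGGAATATGGCGAGAAA
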