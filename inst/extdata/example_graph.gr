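p tw 8 10
1 3
1 5
1 8
2 3
2 8
3 5
3 6
3 8
4 7
5 8
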