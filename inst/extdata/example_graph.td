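s td 8 4 8
b 1 1 3 5 8
b 2 3 5 8
b 3 2 3 8
b 4 3 6
b 5 4 7
b 6 3 8
b 7 4
b 8 8
1 2
2 6
3 6
4 6
5 7
6 8
7 8
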