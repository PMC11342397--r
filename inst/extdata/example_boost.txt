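# frame deltaV(kcal/mol)
0 0.000
1 0.500
2 1.000
3 1.500
4 2.000
5 2.500
6 3.000
7 3.500
8 4.000
9 4.500
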