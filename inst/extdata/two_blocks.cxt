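B

6
6

g0
g1
g2
g3
g4
g5
m0
m1
m2
m3
m4
m5
XXXX..
XXXX..
XXXXXX
XXXXXX
..XXXX
..XXXX
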