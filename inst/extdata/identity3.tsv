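# 3x3 identity bipartite network: three disjoint links
g1	m1
g2	m2
g3	m3
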