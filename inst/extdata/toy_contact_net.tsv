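# synthetic toy contact network (hand-constructed, 14 nodes)
# hub with pendant nodes, a triangle-rich core and a short chain
hub p1
hub p2
hub p3
hub c1
c1 c2
c2 c3
c3 c1
c1 c4
c4 c5
c5 c2
c3 c6
c6 c7
c7 c8
c8 q1
q1 q2
hub c6
c4 c6
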