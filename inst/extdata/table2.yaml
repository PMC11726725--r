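# Self-replication scenario: Table 1 chemistry plus replication/decay of A
A0: 7.0
cX: 100
cY: 24.45
kRR: 1
dR: 0.01
k1: 1
k2: 1
k3: 1
k4: 1
dt: 0.001
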