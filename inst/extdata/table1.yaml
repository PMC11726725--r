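# Spreadsheet-scenario parameter set (deterministic binding network)
dt: 0.001
k1: 1
k2: 1
k3: 1
k4: 1
cX: 100
cY: 24.45
cA: 7
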