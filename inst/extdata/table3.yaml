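# Multi-agent scenario parameter set
sizeX: 1050
sizeY: 675
init_R: 2250
init_P: 112
agent_size: 3.0
Nmax: 4
d: 0.1
aR: 0.8
aP: 0.8
lP: 0.2
D: 400
Dprime: 400
delta: 0.1
dt: 1
K_repl: 1
k1: 10
k2: 5
k3: 10
k4: 5
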