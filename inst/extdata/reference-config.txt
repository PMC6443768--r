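# Reference experiment: return sweep on a 4-neighbor periodic lattice,
# 1% initial cooperators placed at random.
r_min = 1
r_max = 6
r_step = 0.5
delta = 0.05
d = 0
h = 2
network_model = square4
n = 1024
init_scheme = random
init_fraction = 0.01
max_rounds = 10000
replicates = 20
seed = 1
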