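# Avascular spheroid growth in a nutrient bath (Dirichlet u_n = 0.5).
# High hypoxic thresholds make the spheroid stall and die off; low ones
# keep a proliferative surface hull alive.
scenario: spheroid
u_n_H: 0.15
n_cells: 200
days: 30
seed: 1
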