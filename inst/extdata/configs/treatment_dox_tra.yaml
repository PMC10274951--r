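# Chemotherapy first, antibody second: the DOX dose has decayed before the
# supply factor charges, so the combination behaves like TRA alone.
scenario: treatment
protocol: DOX_TRA
days: 14
seed: 1
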