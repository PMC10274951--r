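# Sprouting angiogenesis around a hypoxic, VEGF-secreting spheroid with the
# vessel VEGF sink enabled (the sink makes the network diffuse and
# tumor-surrounding).
scenario: angiogenesis
vegf_sink: true
days: 10
seed: 1
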