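# Untreated control for the protocol comparison.
scenario: treatment
protocol: untreated
days: 14
seed: 1
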