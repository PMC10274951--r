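# Combination therapy, anti-angiogenic agent first: TRA in delivery slots 1
# and 2, DOX in slot 3 (the most effective ordering).
scenario: treatment
protocol: TRA_DOX
days: 14
seed: 1
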