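# Anti-HER2 antibody alone: TRA in all three delivery slots; growth stalls
# through the proliferation suppression but little extra death occurs.
scenario: treatment
protocol: TRA
days: 14
seed: 1
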