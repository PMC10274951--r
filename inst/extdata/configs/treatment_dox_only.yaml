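# Chemotherapy alone: DOX in all three delivery slots; with its short
# half-life and unimproved vascular supply this protocol is ineffective.
scenario: treatment
protocol: DOX
days: 14
seed: 1
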