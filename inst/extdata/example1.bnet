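# 3-node demonstration network: A represses itself through B, and the
# A/B pair drives C, giving a single limit cycle of period 5.
targets, factors
A, !B
B, A & C
C, A | B
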