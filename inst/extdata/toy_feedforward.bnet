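# 6-node feedforward toy: two constant signal nodes (S1, S2) feed two
# middle-layer gates whose outputs converge on the terminal pair A, B.
# The terminal ladder of its product-basis equations mirrors the shape
# seen in feedforward arms of signalling models.
targets, factors
S1, S1
S2, S2
M1, S1 & S2
M2, S1 | S2
A, M1 | M2
B, M1 & S2
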