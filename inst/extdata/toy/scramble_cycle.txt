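# TCA-like cycle: condensation of a two-carbon donor onto a recycled
# two-carbon acceptor (convolution node) followed by a symmetric
# four-carbon intermediate written as two half-weight mapping variants.
SOURCE T 2
SOURCE U 2
SINK W 2
R1: T (ab) -> A (ab)
R2: U (ab) -> O (ab)
R3: O (ab) + A (cd) -> K (abcd)
R4[0.5]: K (abcd) -> F (abcd)
R4[0.5]: K (abcd) -> F (dcba)
R5: F (abcd) -> O (ab) + W (cd)
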