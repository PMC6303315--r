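# Cleave-then-recombine: a one-carbon unit split from a three-carbon pool
# mixes with an unlabeled one-carbon source before recombination
# (serine/glycine/one-carbon-like motif with a convolution node).
SOURCE T 3
SOURCE U 1
SINK Q 3
R1: T (abc) -> P (abc)
R2: P (abc) -> G (ab) + M (c)
R3: U (a) -> M (a)
R4: G (ab) + M (c) -> Q (abc)
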