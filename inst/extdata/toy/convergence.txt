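# Two-input pool: a labeled route and an unlabeled route converge
# (de novo synthesis versus uptake).
SOURCE T 3
SOURCE U 3
SINK Q 3
R1: T (abc) -> P (abc)
R2: U (abc) -> P (abc)
R3: P (abc) -> Q (abc)
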