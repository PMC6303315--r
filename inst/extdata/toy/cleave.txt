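# Decarboxylating cleavage: carbon 1 of the three-carbon pool routes to a
# one-carbon waste product (pyruvate-dehydrogenase-like step).
SOURCE S 3
SINK E 2
SINK C1 1
R1: S (abc) -> P (abc)
R2: P (abc) -> X (bc) + C1 (a)
R3: X (ab) -> E (ab)
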