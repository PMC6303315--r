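# Linear two-carbon chain: identity transfers only.
SOURCE A 2
SINK C 2
R1: A (ab) -> B (ab)
R2: B (ab) -> C (ab)
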