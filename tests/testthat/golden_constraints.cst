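AtomPair CA 1 CA 3 FLAT_HARMONIC 4.5 3 5
AtomPair CA 1 CA 4 FLAT_HARMONIC 10 3 5
AtomPair CA 2 CA 5 FLAT_HARMONIC 10 3 5
AtomPair CA 3 CA 6 FLAT_HARMONIC 10 3 5
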