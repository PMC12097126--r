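# polyA-signal hexamer catalog, priority order (strongest first).
# Seeded from the PolyASite signal compendium -- verify against PolyASite
# before use on real data; substitute your own list via the `catalog`
# arguments if needed. DNA alphabet.
AATAAA
ATTAAA
TATAAA
AGTAAA
AATACA
CATAAA
AATATA
GATAAA
AATGAA
TTTAAA
ACTAAA
AATAGA
AATAAT
AACAAA
ATTACA
ATTATA
AACAAG
AATAAG
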