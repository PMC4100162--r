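# Active-site annotation for cysteine protease 1 from Zea mays (zmCP1),
# mature-chain numbering on chain A.
catalytic_triad: A:149 A:285 A:306
oxyanion_hole: A:143 A:149
subsite S1: A:147 A:189 A:190 A:191
# S2 per the in-text five-residue list (Leu193, Met194, Ala259, Leu283,
# Ala286); a four-residue variant without Ala259 also appears in figure
# annotations of the same study.  Edit this line to use the narrow set.
subsite S2: A:193 A:194 A:259 A:283 A:286
nucleophile: A:149 SG
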