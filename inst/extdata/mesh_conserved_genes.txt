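# Six additional conserved cisplatin-associated genes contributed by the
# supplemental MeSH cisplatin set beyond the CTD triple intersection.
GJA1
CCN1
H2AX
IL10
WRN
HSP90AA1
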