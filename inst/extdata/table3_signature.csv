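# The 13-gene resistant-subtype signature with the direction of
# differential expression in each resistant subtype (M, LAR); NONE means
# the gene is not differentially expressed in that subtype.
gene,M,LAR
ABCC2,NONE,UP
AKT1,NONE,UP
BCL2L1,NONE,UP
CASP8,DOWN,UP
CLU,NONE,UP
FAS,DOWN,NONE
GSR,NONE,UP
MSH2,NONE,DOWN
NOX4,UP,NONE
NQO1,NONE,UP
TUBA1A,UP,DOWN
VCAM1,DOWN,NONE
VIM,UP,DOWN
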