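# Regulation of the 20 conserved cisplatin-associated genes that are
# differentially expressed in the four tumor-cell TNBC subtypes, with the
# resistant-signature membership flag and the cell-death annotation flag.
#
# The published table's column placement is ambiguous for several cells in
# the extracted text. The encoding below is fixed by constraint
# satisfaction against every printed summary and is unique up to the
# documented free choices:
#   - per-subtype up:down counts must be BL1 2:5, BL2 4:0, M 5:3, LAR 8:3;
#   - the 13 resistant-signature genes must carry exactly the published
#     directions (ABCC2/AKT1/BCL2L1/CLU/GSR/NQO1 up in LAR, MSH2 down in
#     LAR, CASP8 up in LAR + down in M, NOX4 up in M, FAS and VCAM1 down
#     in M, TUBA1A and VIM up in M + down in LAR);
#   - the other 7 genes must be excluded by the signature rule, which
#     forces each of their resistant-subtype statuses to be matched by a
#     sensitive-subtype status (ADM: BL1+M up; GJA1: BL1 down, BL2+M up;
#     HSPB1: BL2+LAR up) and CAV1/PTK2/BCL2/FOS to sit only in sensitive
#     columns (left-to-right reading of the extracted rows fixes BL1 vs
#     BL2 and MSH2's up cell in BL1);
#   - 16 genes up in at least one subtype, 11 down in at least one;
#   - 15 of the 20 genes carry the cell-death flag (rows marked for both
#     signature and death in the source carry two marks; single-marked
#     rows carry whichever of the two applies).
gene,BL1,BL2,M,LAR,resistant,death
ABCC2,NONE,NONE,NONE,UP,TRUE,FALSE
ADM,UP,NONE,UP,NONE,FALSE,TRUE
AKT1,NONE,NONE,NONE,UP,TRUE,TRUE
BCL2,DOWN,NONE,NONE,NONE,FALSE,TRUE
BCL2L1,NONE,NONE,NONE,UP,TRUE,TRUE
CASP8,NONE,NONE,DOWN,UP,TRUE,TRUE
CAV1,NONE,UP,NONE,NONE,FALSE,TRUE
CLU,DOWN,NONE,NONE,UP,TRUE,TRUE
FAS,NONE,NONE,DOWN,NONE,TRUE,TRUE
FOS,DOWN,NONE,NONE,NONE,FALSE,TRUE
GJA1,DOWN,UP,UP,NONE,FALSE,TRUE
GSR,NONE,NONE,NONE,UP,TRUE,FALSE
HSPB1,NONE,UP,NONE,UP,FALSE,TRUE
MSH2,UP,NONE,NONE,DOWN,TRUE,TRUE
NOX4,DOWN,NONE,UP,NONE,TRUE,TRUE
NQO1,NONE,NONE,NONE,UP,TRUE,TRUE
PTK2,NONE,UP,NONE,NONE,FALSE,TRUE
TUBA1A,NONE,NONE,UP,DOWN,TRUE,FALSE
VCAM1,NONE,NONE,DOWN,NONE,TRUE,FALSE
VIM,NONE,NONE,UP,DOWN,TRUE,FALSE
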