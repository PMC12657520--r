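# Synthetic stand-in for the 119-gene ERK-dependent DEG list
# (load-upregulated AND inhibitor-downregulated); the six overlapping
# TFs are listed first. One symbol per line.
NR4A1
CEBPD
KLF9
ZNF331
IRF1
NR6A1
ACTA2
FN1
COL1A1
COL1A2
COL3A1
COL5A1
TAGLN
CCN1
CCN2
SERPINE1
TNC
POSTN
LOX
LOXL2
TIMP1
TIMP3
MMP2
MMP14
ITGA5
ITGB1
ITGAV
VCL
TLN1
ZYX
LMNA
CAV1
YAP1
WWTR1
EGR1
EGR2
FOS
FOSB
JUNB
ATF3
DUSP1
DUSP5
DUSP6
SPRY2
SPRY4
ETV4
ETV5
IER2
IER3
KLF2
KLF4
KLF6
MYC
CCND1
PDGFA
PDGFB
PDGFRB
TGFB1
TGFBI
INHBA
LTBP2
THBS1
THBS2
SPARC
FBN1
ELN
EMILIN1
FBLN2
NID1
LAMC1
HSPG2
VCAN
HAS2
CD44
SDC1
SDC4
ITGA11
TNFAIP3
NFKBIA
SOCS3
CISH
PIM1
BCL3
GADD45B
PLK2
PLK3
RND1
RND3
ARHGAP29
RHOB
RHOC
LIMK1
CFL1
PFN1
MYL9
MYH9
TPM1
TPM2
CNN1
LMOD1
PALLD
FHL2
CSRP1
LPP
PDLIM7
ACTN1
ACTN4
FLNA
FLNC
SYNPO
SVIL
MICAL2
MRTFA
SRF
TEAD1
AXL
GAS6
F3
PLAU
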