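# Default panel: 59 canonical direct transcriptional targets of p53.
# One symbol per line; edit or replace to match a study-specific panel.
CDKN1A
MDM2
BAX
BBC3
PMAIP1
GADD45A
SFN
SESN1
SESN2
SESN3
TP53I3
TIGAR
RRM2B
DDB2
XPC
POLH
FAS
TNFRSF10A
TNFRSF10B
TNFRSF10C
APAF1
CASP6
PERP
ZMAT3
BTG2
PLK2
PLK3
TP53INP1
TRIAP1
GDF15
SERPINB5
THBS1
IGFBP3
AEN
FDXR
TP53AIP1
PIDD1
ACER2
FUCA1
PHLDA3
RPS27L
TRIM22
CCNG1
PPM1D
GLS2
DRAM1
LIF
EDA2R
ASCC3
EI24
CYFIP2
NINJ1
PTCHD4
RAP2B
GPR87
SIVA1
TP53TG1
BLOC1S2
DDIT4
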