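# Placeholder 43-gene AR pathway signature for testing only (synthetic
# stand-in assembled from well-known androgen-responsive genes; the
# published signature is an input file the user supplies).
KLK3
KLK2
TMPRSS2
NKX3-1
FKBP5
PMEPA1
NDRG1
STEAP1
STEAP2
STEAP4
ZBTB16
CAMKK2
SLC45A3
ELL2
ABCC4
HERC3
PTGER4
EAF2
MED28
MPHOSPH9
ACSL3
TNK1
GNMT
ADAM7
C1orf116
SPOCK1
MAF
PIP
SEC14L2
NNMT
LRIG1
AQP3
SPDEF
ORM1
ORM2
TARP
CHRNA2
SORD
ALDH1A3
KRT19
MAK
AZGP1
UAP1
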