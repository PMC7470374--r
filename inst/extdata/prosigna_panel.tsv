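# Prosigna-style 46-reporter + 8-housekeeping panel.
# Reporter roster reconstructed from the published PAM50 gene set (Parker et al. 2009),
# dropping BAG1, BCL2, MDM2, MYC to reach the 46-gene algorithm panel; the exact
# published 4-gene exclusion is not verifiable offline, so treat the roster as a
# reconstruction. The 18 proliferation genes and 8 housekeepers are the published sets.
# base_center/base_scale are SYNTHETIC per-gene log2 location/gain constants used by
# the cohort generator (not vendor values).
gene	role	base_center	base_scale
ANLN	proliferation	1.25	0.88
BIRC5	proliferation	0.26	1.34
CCNB1	proliferation	-0.62	0.91
CCNE1	proliferation	0.75	1.28
CDC20	proliferation	1.08	1.16
CDC6	proliferation	-0.59	1.08
CEP55	proliferation	-0.82	0.87
EXO1	proliferation	-1.22	1.10
KIF2C	proliferation	-0.05	0.87
MELK	proliferation	-0.20	1.15
MKI67	proliferation	0.80	0.78
NDC80	proliferation	0.04	1.20
NUF2	proliferation	0.26	1.25
ORC6	proliferation	1.29	0.77
PTTG1	proliferation	-0.14	1.06
RRM2	proliferation	0.46	0.72
TYMS	proliferation	-1.39	1.03
UBE2C	proliferation	-1.10	1.10
ESR1	luminal	-0.29	1.29
PGR	luminal	-0.58	0.91
FOXA1	luminal	1.37	0.79
NAT1	luminal	0.07	0.80
SLC39A6	luminal	-0.39	0.93
MAPT	luminal	-1.28	0.96
MLPH	luminal	0.43	1.11
CXXC5	luminal	-0.36	1.24
BLVRA	luminal	-0.95	1.36
GPR160	luminal	-0.75	1.24
TMEM45B	luminal	-0.42	0.72
ERBB2	her2	-0.27	1.01
GRB7	her2	-1.41	0.72
FGFR4	her2	0.62	0.83
KRT5	basal	0.58	0.81
KRT14	basal	-1.11	1.05
KRT17	basal	-0.49	0.72
FOXC1	basal	-1.04	1.25
MIA	basal	1.24	1.37
SFRP1	basal	-0.29	0.93
EGFR	basal	1.42	0.72
CDH3	basal	0.66	0.87
PHGDH	basal	-0.48	1.31
ACTR3B	basal	0.65	1.32
CENPF	other	-1.32	1.06
MYBL2	other	-0.35	0.96
UBE2T	other	-0.48	1.23
MMP11	other	-0.65	0.78
ACTB	housekeeping	NA	NA
MRPL19	housekeeping	NA	NA
PSMC4	housekeeping	NA	NA
RPLP0	housekeeping	NA	NA
SF3A1	housekeeping	NA	NA
GUSB	housekeeping	NA	NA
PUM1	housekeeping	NA	NA
TFRC	housekeeping	NA	NA
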