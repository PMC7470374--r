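# SYNTHETIC subtype centroids (46 genes x 4 intrinsic subtypes), row-scaled units.
# Stand-ins for the published Prosigna/PAM50 centroids (Parker et al. 2009;
# patent US20130337444A1), which are not redistributable/obtainable here.
# Structure (gene order, subtype columns) matches the real object; values are
# biologically patterned but synthetic.
gene	LumA	LumB	Her2E	Basal
ANLN	-0.67	0.76	0.36	1.09
BIRC5	-0.7	0.33	0.22	0.78
CCNB1	-0.64	0.71	0.58	1.01
CCNE1	-0.62	0.48	0.24	0.83
CDC20	-0.72	0.68	0.28	1.07
CDC6	-1.04	0.39	0.38	0.97
CEP55	-0.77	0.77	0.5	0.8
EXO1	-0.91	0.76	0.36	0.89
KIF2C	-0.92	0.71	0.61	1.09
MELK	-1.06	0.32	0.35	0.74
MKI67	-0.77	0.31	0.62	0.84
NDC80	-0.71	0.4	0.38	1.09
NUF2	-0.89	0.35	0.42	0.97
ORC6	-0.93	0.39	0.36	0.79
PTTG1	-0.9	0.39	0.23	0.68
RRM2	-0.83	0.59	0.48	1
TYMS	-1.02	0.67	0.59	1.04
UBE2C	-1.06	0.71	0.3	0.87
ESR1	1.15	0.64	-0.63	-1.04
PGR	0.92	0.74	-0.63	-1.06
FOXA1	0.93	0.67	-0.64	-0.96
NAT1	1.04	0.76	-0.48	-1.18
SLC39A6	0.72	0.51	-0.37	-0.83
MAPT	0.85	0.62	-0.36	-0.77
MLPH	0.65	0.58	-0.64	-1.19
CXXC5	1.05	0.5	-0.51	-1.05
BLVRA	1.15	0.45	-0.52	-1.1
GPR160	1.06	0.69	-0.37	-0.99
TMEM45B	0.69	0.41	-0.25	-1.18
ERBB2	-0.14	-0.04	1.13	-0.38
GRB7	-0.12	0.12	1.48	-0.13
FGFR4	-0.24	0.06	1.17	-0.39
KRT5	-0.65	-0.26	-0.26	1.21
KRT14	-0.37	-0.41	-0.14	1.35
KRT17	-0.3	-0.33	-0.38	1.37
FOXC1	-0.35	-0.29	-0.37	1.06
MIA	-0.75	-0.3	-0.42	1.31
SFRP1	-0.46	-0.56	-0.17	1.53
EGFR	-0.76	-0.66	-0.26	1.42
CDH3	-0.31	-0.36	-0.18	1.08
PHGDH	-0.76	-0.44	-0.02	1.11
ACTR3B	-0.41	-0.7	-0.48	1.32
CENPF	-1.06	0.3	0.67	0.93
MYBL2	-0.83	0.67	0.49	0.65
UBE2T	-0.75	0.59	0.36	1.01
MMP11	0.05	-0.04	0.32	-0.06
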