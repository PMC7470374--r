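# SYNTHETIC generative constants for reporter genes outside the Prosigna panel:
# latent subtype mean profiles (row-scaled units), per-gene log2 location/gain,
# and a bimodal mixture component (GSTM1's below-background mode). Used only by
# the synthetic cohort generator.
gene	LumA	LumB	Her2E	Basal	base_center	base_scale	bimodal_prob	bimodal_shift
AURKA	-0.62	0.37	0.29	0.66	-1.08	1.39	0	0
BCL2	0.62	0.59	-0.28	-0.66	-0.92	1.3	0	0
SCUBE2	0.93	0.11	-0.35	-0.76	-0.85	1.02	0	0
CTSV	0	0	0	0	-4	0.15	0	0
CD68	0.09	0.12	0.15	0.18	-0.73	0.85	0	0
GSTM1	0	0	0	0	1.22	0.95	0.5	-3
BAG1	0.82	0.57	-0.75	-0.59	-0.14	1.25	0	0
CCNE2	-0.58	0.6	0.59	0.94	-0.88	0.72	0	0
MCM6	-0.87	0.57	0.65	0.92	-1.48	0.86	0	0
DTL	-0.76	0.38	0.24	0.92	0.18	0.92	0	0
RFC4	-0.97	0.55	0.41	1.09	0.81	0.81	0	0
GMPS	-0.63	0.47	0.36	0.88	-1.32	0.72	0	0
DIAPH3	-0.9	0.69	0.2	0.7	1.2	1.07	0	0
CDCA7	-0.88	0.4	0.24	0.87	0.86	1.01	0	0
LIN9	-0.82	0.47	0.31	1.07	-1.45	1.22	0	0
DCK	-0.99	0.47	0.32	1.08	0.85	1.26	0	0
PRC1	-0.89	0.67	0.23	0.82	-1.25	0.94	0	0
NUSAP1	-0.87	0.55	0.36	0.71	0.19	1.17	0	0
CENPA	-0.95	0.31	0.53	0.78	-1.2	1.22	0	0
ECT2	-0.73	0.48	0.37	0.63	-0.66	1.18	0	0
EXT1	-0.65	0.43	0.55	0.93	0.46	1.33	0	0
NMU	-0.77	0.76	0.37	1.02	0.21	0.84	0	0
UCHL5	-0.94	0.48	0.46	0.89	1.28	0.75	0	0
FLT1	-0.52	0.24	0.46	0.55	0.48	1.38	0	0
MMP9	-0.59	0.05	0.4	0.61	-1.03	0.89	0	0
WISP1	-0.36	-0.04	0.25	0.8	0.85	1.17	0	0
FGF18	-0.31	0.37	0.6	0.55	-0.64	1.14	0	0
ESM1	-0.66	-0.05	0.33	0.86	1.04	0.98	0	0
GNAZ	-0.41	0.04	0.53	0.66	0.33	1.03	0	0
STK32B	-0.51	0.07	0.37	0.91	0.22	1.31	0	0
RASSF7	-0.63	-0.04	0.67	0.48	1.31	0.87	0	0
SLC2A3	-0.41	-0.08	0.64	0.94	1.37	1.27	0	0
MTDH	-0.29	0.33	0.35	0.68	0.46	1.2	0	0
QSOX2	-0.62	0	0.65	0.8	-0.11	0.93	0	0
ALDH4A1	-0.27	0.11	0.52	0.71	-0.44	1.18	0	0
COL4A2	-0.53	0.22	0.41	0.76	-0.05	1	0	0
HRASLS	-0.49	0.33	0.34	0.49	-1.26	0.74	0	0
LGP2	-0.23	0.38	0.56	0.5	-1.11	1	0	0
GPR126	-0.29	0.01	0.56	0.5	-0.96	1.4	0	0
JHDM1D	-0.54	0.38	0.64	0.69	1.1	0.81	0	0
AYTL2	-0.46	0.3	0.53	0.75	0.84	1.09	0	0
IGFBP5	0.79	0.48	-0.42	-0.58	-0.18	1.37	0	0
BBC3	0.58	0.44	-0.33	-0.87	0.34	1.36	0	0
EGLN1	0.83	0.36	-0.27	-0.9	0.26	1.19	0	0
TGFB3	1.04	0.31	-0.26	-0.97	-0.39	1.25	0	0
GSTM3	0.85	0.35	-0.48	-1.02	-0.52	1.23	0	0
PITRM1	0.63	0.46	-0.54	-0.72	1.18	0.71	0	0
TSPYL5	0.92	0.11	-0.66	-0.62	-0.91	0.88	0	0
OXCT1	0.85	0.34	-0.56	-0.84	-0.48	1.34	0	0
GPR180	0.82	0.39	-0.35	-0.82	1.46	1.28	0	0
ZNF533	0.62	0.54	-0.73	-0.61	0.57	1.38	0	0
PECI	1.03	0.39	-0.46	-0.91	0.71	1.31	0	0
CDC42BPA	0.77	0.55	-0.39	-0.89	-0.61	0.73	0	0
PALM2	0.77	0.31	-0.42	-0.81	0.3	1.25	0	0
RAB6B	0.74	0.21	-0.4	-0.7	0.47	0.8	0	0
SERF1A	0.69	0.42	-0.72	-0.7	-1.3	1.17	0	0
MS4A7	0.92	0.27	-0.5	-0.58	0.72	0.98	0	0
AP2B1	0.68	0.29	-0.71	-0.59	-0.37	1.12	0	0
RUNDC1	0.87	0.22	-0.45	-0.74	-0.33	1.23	0	0
RTN4RL1	0.87	0.28	-0.57	-0.62	-1.18	1.25	0	0
EBF4	0.69	0.52	-0.54	-0.89	0.24	1.27	0	0
FBXO31	1	0.54	-0.49	-0.94	1.09	0.78	0	0
KDM7A	0.93	0.49	-0.33	-0.64	-1.48	1.25	0	0
LPCAT1	0.57	0.42	-0.43	-0.75	0.42	1.08	0	0
MED13L	0.57	0.18	-0.33	-1	0.88	0.97	0	0
SLC16A10	0.64	0.26	-0.57	-1.03	0.04	0.89	0	0
STARD13	0.92	0.23	-0.31	-1	-1.22	1.04	0	0
TLE1	0.66	0.16	-0.46	-0.78	-0.38	1.17	0	0
TMC6	0.68	0.28	-0.41	-0.92	-0.8	1.07	0	0
TPRG1	0.63	0.36	-0.28	-0.69	0.85	1.33	0	0
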