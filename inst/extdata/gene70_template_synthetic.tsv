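# SYNTHETIC gene70 good-prognosis template: standardized LumA mean profile of the
# synthetic 70-gene panel. Stand-in for the published average good-prognosis
# profile (van de Vijver 2002); same role and scale, synthetic values.
gene	value
MELK	-0.9854
NUF2	-0.9587
NDC80	-0.9238
ORC6	-0.9743
EXO1	-1.0004
CCNE2	-0.9514
MCM6	-0.9961
DTL	-0.9276
RFC4	-0.9922
GMPS	-0.9251
DIAPH3	-0.9825
CDCA7	-0.9572
LIN9	-0.9541
DCK	-0.9812
PRC1	-0.9832
NUSAP1	-0.9831
CENPA	-0.9713
ECT2	-0.9521
EXT1	-0.9331
NMU	-0.9824
UCHL5	-0.9891
EGFR	-0.3957
FLT1	-0.8409
MMP9	-0.7931
WISP1	-0.5755
FGF18	-0.8009
ESM1	-0.7682
GNAZ	-0.6922
STK32B	-0.7508
RASSF7	-0.7717
SLC2A3	-0.6212
MTDH	-0.7526
QSOX2	-0.785
ALDH4A1	-0.6371
COL4A2	-0.8335
HRASLS	-0.8474
LGP2	-0.7552
GPR126	-0.5792
JHDM1D	-0.8988
AYTL2	-0.8416
SCUBE2	0.857
IGFBP5	0.6141
BBC3	0.4834
EGLN1	0.6917
TGFB3	0.8034
GSTM3	0.7081
PITRM1	0.522
TSPYL5	0.8555
OXCT1	0.722
GPR180	0.6772
ZNF533	0.467
PECI	0.7723
CDC42BPA	0.5521
PALM2	0.6968
RAB6B	0.7382
SERF1A	0.5923
MS4A7	0.7952
AP2B1	0.6633
RUNDC1	0.7924
RTN4RL1	0.7671
EBF4	0.5256
FBXO31	0.6871
KDM7A	0.6877
LPCAT1	0.4975
MED13L	0.6412
SLC16A10	0.6493
STARD13	0.7907
TLE1	0.7217
TMC6	0.6584
TPRG1	0.5733
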