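# SYNTHETIC MammaPrint-style 70-gene panel roster.
# The true 70-gene list (van 't Veer 2002 / van de Vijver 2002) is not verifiable
# offline; this roster is a synthetic reconstruction sharing a handful of genuine
# members and the panel's size/structure. Swap for the real roster when available.
gene
MELK
NUF2
NDC80
ORC6
EXO1
CCNE2
MCM6
DTL
RFC4
GMPS
DIAPH3
CDCA7
LIN9
DCK
PRC1
NUSAP1
CENPA
ECT2
EXT1
NMU
UCHL5
EGFR
FLT1
MMP9
WISP1
FGF18
ESM1
GNAZ
STK32B
RASSF7
SLC2A3
MTDH
QSOX2
ALDH4A1
COL4A2
HRASLS
LGP2
GPR126
JHDM1D
AYTL2
SCUBE2
IGFBP5
BBC3
EGLN1
TGFB3
GSTM3
PITRM1
TSPYL5
OXCT1
GPR180
ZNF533
PECI
CDC42BPA
PALM2
RAB6B
SERF1A
MS4A7
AP2B1
RUNDC1
RTN4RL1
EBF4
FBXO31
KDM7A
LPCAT1
MED13L
SLC16A10
STARD13
TLE1
TMC6
TPRG1
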