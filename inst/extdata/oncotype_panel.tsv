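# Oncotype DX 16-gene + 5-reference panel with within-metagene averaging weights
# (Paik et al. 2004: HER2 group = 0.9*GRB7 + 0.1*ERBB2; ER group =
# (0.8*ESR1 + 1.2*PGR + BCL2 + SCUBE2)/4; proliferation and invasion groups are
# unweighted means). CTSV is Cathepsin-L2.
gene	role	avg_weight
MKI67	proliferation	1
AURKA	proliferation	1
BIRC5	proliferation	1
CCNB1	proliferation	1
MYBL2	proliferation	1
GRB7	her2	0.9
ERBB2	her2	0.1
ESR1	er	0.8
PGR	er	1.2
BCL2	er	1
SCUBE2	er	1
MMP11	invasion	1
CTSV	invasion	1
CD68	cd68	1
GSTM1	gstm1	1
BAG1	bag1	1
ACTB	housekeeping	NA
GAPDH	housekeeping	NA
RPLP0	housekeeping	NA
GUSB	housekeeping	NA
TFRC	housekeeping	NA
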