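# Explicit gene-symbol alias table (no fuzzy matching).
alias	canonical
CTSL2	CTSV
STK15	AURKA
ORC6L	ORC6
KNTC2	NDC80
CDCA1	NUF2
KI-67	MKI67
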