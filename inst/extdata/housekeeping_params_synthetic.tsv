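# SYNTHETIC housekeeping baseline log2 intensities for the cohort generator.
# Low between-sample variance is imposed at generation time.
gene	log2_level
ACTB	12.5
MRPL19	8.5
PSMC4	9.2
RPLP0	12
SF3A1	8.8
GUSB	9.5
PUM1	8.3
TFRC	9
GAPDH	12.8
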