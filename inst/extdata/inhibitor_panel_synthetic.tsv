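# Synthetic stand-in inhibitor panel: 15 targets of the screen
inhibitor	target	class
NR4A1-IN-1	NR4A1	TF
STAT3-IN-1	STAT3	TF
GATA3-IN-1	GATA3	TF
NFATC1-IN-1	NFATC1	TF
FOXO1-IN-1	FOXO1	TF
TP53-IN-1	TP53	TF
STAT1-IN-1	STAT1	TF
JUN-IN-1	JUN	TF
SMAD3-IN-1	SMAD3	TF
HIF1A-IN-1	HIF1A	TF
SIN3A-IN-1	SIN3A	TF
NCOR1-IN-1	NCOR1	TF
SRC-IN-1	SRC	kinase
PDK1-IN-1	PDK1	kinase
HDAC2-IN-1	HDAC2	chromatin modifier
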