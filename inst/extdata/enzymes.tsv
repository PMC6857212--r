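enzyme	motif
EcoRI	GAATTC
BamHI	GGATCC
HindIII	AAGCTT
TaqI	TCGA
MseI	TTAA
FokI	GGATG
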