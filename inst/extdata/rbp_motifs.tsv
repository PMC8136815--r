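name	pattern
RBFOX	TGCATG
PTBP1	TCTTC
NOVA1	YCAYC
QKI	ACTAAY
MBNL1	YGCTTGC
CELF1	TGTGTG
HNRNPA1	TAGGGA
HNRNPC	TTTTT
TIA1	TTTTA
ELAVL1	TTTATTT
SRSF1	GGAGGA
SRSF2	GGCCTCTG
SRSF7	ACGACG
TRA2B	GAAGAA
U2AF2	TTTTCC
KHDRBS1	ATAAAA
PCBP1	CCCTCC
ESRP2	GGTGGTG
SAMD4A	GCACCA
FUS	GGTGGT
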