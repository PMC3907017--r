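triplet	weight
TTT	5.69
TTC	32.22
TTA	3.01
TTG	3.01
CTT	3.01
CTC	85.17
CTA	3.01
CTG	3.01
ATT	3.32
ATC	37.65
ATA	3.32
ATG	22
GTT	3.04
GTC	51.59
GTA	3.04
GTG	3.04
TCT	2.43
TCC	2.43
TCA	2.43
TCG	2.43
CCT	3.05
CCC	51.94
CCA	3.05
CCG	3.05
ACT	2.66
ACC	45.22
ACA	2.66
ACG	2.66
GCT	3.46
GCC	58.9
GCA	3.46
GCG	3.46
TAT	4.12
TAC	23.38
TAA	1
TAG	0.8
CAT	3.9
CAC	22.1
CAA	6.97
CAG	39.52
AAT	5.42
AAC	30.68
AAA	8.44
AAG	47.85
GAT	7.04
GAC	39.87
GAA	10.29
GAG	58.31
TGT	3.48
TGC	19.72
TGA	1.6
TGG	13.2
CGT	1.7
CGC	48.2
CGA	1.7
CGG	1.7
AGT	2.43
AGC	68.93
AGA	1.7
AGG	1.7
GGT	3.3
GGC	56.1
GGA	3.3
GGG	3.3
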