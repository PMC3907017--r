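triplet	weight
AAA	0.035937
AAC	0.018513
AAG	0.018513
AAT	0.035937
ACA	0.018513
ACC	0.009537
ACG	0.009537
ACT	0.018513
AGA	0.018513
AGC	0.009537
AGG	0.009537
AGT	0.018513
ATA	0.035937
ATC	0.018513
ATG	0.018513
ATT	0.035937
CAA	0.018513
CAC	0.009537
CAG	0.009537
CAT	0.018513
CCA	0.009537
CCC	0.004913
CCG	0.004913
CCT	0.009537
CGA	0.009537
CGC	0.004913
CGG	0.004913
CGT	0.009537
CTA	0.018513
CTC	0.009537
CTG	0.009537
CTT	0.018513
GAA	0.018513
GAC	0.009537
GAG	0.009537
GAT	0.018513
GCA	0.009537
GCC	0.004913
GCG	0.004913
GCT	0.009537
GGA	0.009537
GGC	0.004913
GGG	0.004913
GGT	0.009537
GTA	0.018513
GTC	0.009537
GTG	0.009537
GTT	0.018513
TAA	0.035937
TAC	0.018513
TAG	0.018513
TAT	0.035937
TCA	0.018513
TCC	0.009537
TCG	0.009537
TCT	0.018513
TGA	0.018513
TGC	0.009537
TGG	0.009537
TGT	0.018513
TTA	0.035937
TTC	0.018513
TTG	0.018513
TTT	0.035937
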