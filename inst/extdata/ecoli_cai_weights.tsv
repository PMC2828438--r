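# E. coli relative adaptiveness w (Sharp & Li 1987), the CodonW default
# reference for CAI. Stops and the non-degenerate ATG/TGG carry w = 1 and
# are excluded from the CAI product by convention.
codon	weight
TTT	0.296
TTC	1.000
TTA	0.020
TTG	0.020
CTT	0.042
CTC	0.037
CTA	0.007
CTG	1.000
ATT	0.185
ATC	1.000
ATA	0.003
ATG	1.000
GTT	1.000
GTC	0.066
GTA	0.495
GTG	0.221
TCT	1.000
TCC	0.744
TCA	0.077
TCG	0.017
AGT	0.085
AGC	0.410
CCT	0.070
CCC	0.012
CCA	0.135
CCG	1.000
ACT	0.965
ACC	1.000
ACA	0.076
ACG	0.099
GCT	1.000
GCC	0.122
GCA	0.586
GCG	0.424
TAT	0.239
TAC	1.000
CAT	0.291
CAC	1.000
CAA	0.124
CAG	1.000
AAT	0.051
AAC	1.000
AAA	1.000
AAG	0.253
GAT	0.434
GAC	1.000
GAA	1.000
GAG	0.259
TGT	0.500
TGC	1.000
TGG	1.000
CGT	1.000
CGC	0.356
CGA	0.004
CGG	0.004
AGA	0.004
AGG	0.002
GGT	1.000
GGC	0.724
GGA	0.010
GGG	0.019
TAA	1.000
TAG	1.000
TGA	1.000
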