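# E. coli optimal codons (Ikemura; as used by CodonW for Fop/CBI)
TTC
CTG
ATC
GTT
GTA
TCT
TCC
CCG
ACT
ACC
GCT
GCA
TAC
CAC
CAG
AAC
AAA
GAC
GAA
TGC
CGT
CGC
GGT
GGC
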