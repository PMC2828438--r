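# Static recognition-motif list of common E. coli-relevant restriction
# enzymes and methylation systems (IUPAC). Replaceable: supply your own
# TSV to read_motifs(). Motifs longer than 6 nt never match a hexamer but
# are kept for completeness.
name	recognition	source
EcoRI	GAATTC	type II restriction endonuclease
EcoRII	CCWGG	type II restriction endonuclease
EcoRV	GATATC	type II restriction endonuclease
EcoKI	AACNNNNNNGTGC	type I restriction-modification
Dam	GATC	adenine methyltransferase
Dcm	CCWGG	cytosine methyltransferase
DpnI	GATC	methylation-dependent endonuclease
MboI	GATC	type II restriction endonuclease
Sau3AI	GATC	type II restriction endonuclease
HindII	GTYRAC	type II restriction endonuclease
HindIII	AAGCTT	type II restriction endonuclease
BamHI	GGATCC	type II restriction endonuclease
BglII	AGATCT	type II restriction endonuclease
PstI	CTGCAG	type II restriction endonuclease
SalI	GTCGAC	type II restriction endonuclease
XhoI	CTCGAG	type II restriction endonuclease
SmaI	CCCGGG	type II restriction endonuclease
KpnI	GGTACC	type II restriction endonuclease
SacI	GAGCTC	type II restriction endonuclease
SphI	GCATGC	type II restriction endonuclease
NcoI	CCATGG	type II restriction endonuclease
NdeI	CATATG	type II restriction endonuclease
NheI	GCTAGC	type II restriction endonuclease
SpeI	ACTAGT	type II restriction endonuclease
XbaI	TCTAGA	type II restriction endonuclease
ClaI	ATCGAT	type II restriction endonuclease
AluI	AGCT	type II restriction endonuclease
HaeIII	GGCC	type II restriction endonuclease
HhaI	GCGC	type II restriction endonuclease
HpaII	CCGG	type II restriction endonuclease
MspI	CCGG	type II restriction endonuclease
TaqI	TCGA	type II restriction endonuclease
RsaI	GTAC	type II restriction endonuclease
HinfI	GANTC	type II restriction endonuclease
DdeI	CTNAG	type II restriction endonuclease
AvaII	GGWCC	type II restriction endonuclease
StyI	CCWWGG	type II restriction endonuclease
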