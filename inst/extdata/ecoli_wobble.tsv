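# Curated E. coli codon -> anticodon decoding table.
# Standard Watson-Crick pairing plus wobble rules for the known isoacceptor set:
# cmo5U34 reads A/G/U-ending codons, mnm5(s2)U34 reads A/G, inosine (Arg ACG)
# reads U/C/A, G34 reads C/U. One codon-anticodon pair per line; a codon may
# appear on several lines. Editable package data.
# codon	anticodon
TTT	GAA
TTC	GAA
TTA	UAA
TTG	CAA
TTG	UAA
CTT	GAG
CTT	UAG
CTC	GAG
CTA	UAG
CTG	CAG
CTG	UAG
ATT	GAU
ATC	GAU
ATA	UAU
ATG	CAU
GTT	GAC
GTT	UAC
GTC	GAC
GTA	UAC
GTG	UAC
TCT	UGA
TCT	GGA
TCC	GGA
TCA	UGA
TCG	CGA
TCG	UGA
AGT	GCU
AGC	GCU
CCT	GGG
CCT	UGG
CCC	GGG
CCA	UGG
CCG	CGG
CCG	UGG
ACT	GGU
ACT	UGU
ACC	GGU
ACA	UGU
ACG	CGU
ACG	UGU
GCT	GGC
GCT	UGC
GCC	GGC
GCA	UGC
GCG	UGC
TAT	GUA
TAC	GUA
CAT	GUG
CAC	GUG
CAA	UUG
CAG	CUG
AAT	GUU
AAC	GUU
AAA	UUU
AAG	UUU
GAT	GUC
GAC	GUC
GAA	UUC
GAG	UUC
TGT	GCA
TGC	GCA
TGG	CCA
CGT	ACG
CGC	ACG
CGA	ACG
CGG	CCG
AGA	UCU
AGG	CCU
GGT	GCC
GGC	GCC
GGA	UCC
GGG	CCC
GGG	UCC
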