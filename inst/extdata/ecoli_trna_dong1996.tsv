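# E. coli tRNA abundances, molecules per cell at growth rate 0.4 doublings/h
# (approximate transcription of the classic measurements; relative orderings
#  are what the package relies on, not absolute values).
# anticodon	concentration	note
GGC	617	Ala2
UGC	3250	Ala1B
ACG	4752	Arg2 (inosine at 34; reads CGU/CGC/CGA)
CCG	639	Arg3
UCU	867	Arg4
CCU	420	Arg5
GUU	1193	Asn
GUC	2396	Asp1
GCA	1587	Cys
UUG	764	Gln1
CUG	881	Gln2
UUC	4717	Glu2
GCC	4359	Gly3
UCC	1265	Gly2
CCC	1068	Gly1
GUG	639	His
GAU	1737	Ile1
UAU	409	Ile2 (lysidine-modified CAU; decodes AUA only)
CAG	4470	Leu1
GAG	943	Leu2
UAG	666	Leu3 (rarest Leu isoacceptor; decodes CUA)
CAA	1913	Leu4
UAA	1031	Leu5
UUU	1924	Lys
CAU	706	Met (elongator)
GAA	1037	Phe
CGG	900	Pro1
GGG	720	Pro2
UGG	581	Pro3
UGA	1296	Ser1
CGA	344	Ser2
GCU	1408	Ser3
GGA	764	Ser5
GGU	1100	Thr1/Thr3
CGU	541	Thr2
UGU	916	Thr4
CCA	943	Trp
GUA	2030	Tyr1/Tyr2
UAC	3840	Val1
GAC	1866	Val2A/Val2B
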