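codon	cai
TTT	0.304575
TTC	0.406644
TTA	0.598815
TTG	0.91987
TCT	0.24347
TCC	0.910471
TCA	0.954783
TCG	0.68301
TAT	0.652677
TAC	0.109539
TGT	0.24758
TGC	0.219416
TGG	0.708117
CTT	0.418113
CTC	0.787404
CTA	0.526865
CTG	0.737408
CCT	1
CCC	0.414218
CCA	0.794683
CCG	0.945238
CAT	0.253484
CAC	0.674275
CAA	0.170589
CAG	0.306214
CGT	0.420038
CGC	0.063207
CGA	0.416471
CGG	0.882996
ATT	0.376224
ATC	0.511912
ATA	0.624389
ATG	0.522885
ACT	0.228665
ACC	0.842483
ACA	0.690352
ACG	0.810762
AAT	0.153728
AAC	0.74324
AAA	0.444126
AAG	0.83633
AGT	0.669858
AGC	0.799937
AGA	0.579843
AGG	0.55752
GTT	0.806087
GTC	0.072724
GTA	0.507269
GTG	0.751476
GCT	0.713582
GCC	0.507642
GCA	0.874876
GCG	0.469805
GAT	0.284747
GAC	0.118053
GAA	0.145612
GAG	0.353174
GGT	0.546908
GGC	0.684166
GGA	0.439871
GGG	0.92434
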