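codon	frequency
TTT	0.0425
TTC	0.0343
TTA	0.0101
TTG	0.0186
TCT	0.0342
TCC	0.0035
TCA	0.029
TCG	0.0519
TAT	0.0166
TAC	0.0357
TAA	0.0023
TAG	0.0421
TGT	0.0154
TGC	0.0512
TGA	0.0109
TGG	0.0227
CTT	0.0336
CTC	0.0021
CTA	0.0204
CTG	0.003
CCT	0.0218
CCC	0.0219
CCA	0.0155
CCG	0.0056
CAT	0.0259
CAC	0.0128
CAA	0.0258
CAG	0.0101
CGT	0.0023
CGC	0.0369
CGA	0.0548
CGG	0.0122
ATT	0.0444
ATC	0.0029
ATA	0.036
ATG	0.0267
ACT	0.0142
ACC	0.0297
ACA	0.0458
ACG	0.0279
AAT	0.0235
AAC	0.0527
AAA	0.0272
AAG	0.0275
AGT	0.0068
AGC	0.004
AGA	0.0559
AGG	0.0191
GTT	0.0321
GTC	0.0157
GTA	0.0584
GTG	0.0387
GCT	0.0576
GCC	0.0534
GCA	0.0323
GCG	0.0435
GAT	0.045
GAC	0.0047
GAA	0.0576
GAG	0.0137
GGT	0.0193
GGC	0.0539
GGA	0.0348
GGG	0.0284
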