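triplet	count
ACA	110565151
ACC	122679321
ACG	157596699
ACT	95555375
ATA	88059554
ATC	127442830
ATG	141532621
ATT	84248723
CCA	105178090
CCC	129667559
CCG	67143448
CCT	102389310
CTA	74023039
CTC	72428460
CTG	69511608
CTT	96717286
GCA	107489132
GCC	61806262
GCG	130286062
GCT	102242120
GTA	116030197
GTC	166543756
GTG	76891662
GTT	114338245
TCA	81224501
TCC	72685678
TCG	65434971
TCT	91426356
TTA	104984539
TTC	89037424
TTG	86649109
TTT	103725927
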