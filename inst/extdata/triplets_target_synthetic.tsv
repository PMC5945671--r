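triplet	count
ACA	105492
ACC	50052
ACG	122244
ACT	57872
ATA	80956
ATC	48861
ATG	133037
ATT	72658
CCA	140682
CCC	72868
CCG	61708
CCT	87953
CTA	70161
CTC	170785
CTG	57718
CTT	154588
GCA	106004
GCC	95531
GCG	76132
GCT	44256
GTA	118699
GTC	104070
GTG	179364
GTT	127481
TCA	48965
TCC	124486
TCG	143581
TCT	104607
TTA	84969
TTC	152687
TTG	247485
TTT	123508
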