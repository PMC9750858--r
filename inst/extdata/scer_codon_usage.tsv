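aa	codon	fraction
A	GCT	0.38
A	GCC	0.22
A	GCA	0.29
A	GCG	0.11
R	AGA	0.48
R	AGG	0.21
R	CGT	0.14
R	CGA	0.07
R	CGC	0.06
R	CGG	0.04
N	AAT	0.59
N	AAC	0.41
D	GAT	0.65
D	GAC	0.35
C	TGT	0.63
C	TGC	0.37
Q	CAA	0.69
Q	CAG	0.31
E	GAA	0.70
E	GAG	0.30
G	GGT	0.47
G	GGA	0.22
G	GGC	0.19
G	GGG	0.12
H	CAT	0.64
H	CAC	0.36
I	ATT	0.46
I	ATC	0.26
I	ATA	0.28
L	TTG	0.29
L	TTA	0.28
L	CTA	0.14
L	CTT	0.13
L	CTG	0.10
L	CTC	0.06
K	AAA	0.58
K	AAG	0.42
M	ATG	1.00
F	TTT	0.59
F	TTC	0.41
P	CCA	0.42
P	CCT	0.31
P	CCC	0.15
P	CCG	0.12
S	TCT	0.26
S	TCA	0.21
S	TCC	0.16
S	AGT	0.16
S	AGC	0.11
S	TCG	0.10
T	ACT	0.35
T	ACA	0.30
T	ACC	0.21
T	ACG	0.14
W	TGG	1.00
Y	TAT	0.56
Y	TAC	0.44
V	GTT	0.39
V	GTC	0.21
V	GTA	0.21
V	GTG	0.19
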