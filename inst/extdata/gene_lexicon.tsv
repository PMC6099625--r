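# demonstration gene lexicon: surface form <TAB> concept id (synthetic demo resource)
BRAF	673
KRAS	3845
EGFR	1956
TP53	7157
BRCA1	672
BRCA2	675
ALK	238
MET	4233
RET	5979
KIT	3815
PTEN	5728
PIK3CA	5290
NRAS	4893
HRAS	3265
MYC	4609
ERBB2	2064
CDKN2A	1029
APC	324
VHL	7428
NF1	4763
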