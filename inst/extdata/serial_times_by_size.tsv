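# reference benchmark: serial processing time of three NER tools by input size
# columns: size_mb	gnormplus	tmvar	dnorm	total (seconds)
1	1511.35	239.74	59.51	1812.53
2	2696.64	319.31	62.94	3083.69
4	4944.35	633.57	86.24	5680.40
8	8604.43	985.63	130.33	9742.16
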