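# reference benchmark: serial processing time of three NER tools by article count
# columns: n_papers	gnormplus	tmvar	dnorm	total (seconds)
10	1742.16	416.71	58.29	2219.27
20	2764.13	444.86	65.14	3278.33
40	4865.14	488.08	83.19	5444.17
80	7864.37	744.86	177.45	8803.85
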