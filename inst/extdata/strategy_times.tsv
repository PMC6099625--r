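# reference benchmark: per-strategy execution times on a 16 MB / 175-article corpus
# panel 'max' = maximum time among all processes, 'avg' = average time of all
# processes (seconds); columns: panel	n_procs	random	round_robin	short_board
max	2	8676.60	8651.42	8466.89
max	4	4466.81	5211.96	4596.09
max	8	2792.29	2706.41	2386.45
max	16	1737.94	1457.01	1475.07
max	32	932.85	942.10	930.25
max	64	609.06	579.8	553.42
avg	2	8513.10	8374.08	8392.46
avg	4	4001.38	4535.42	4393.07
avg	8	2287.19	2354.14	2242.42
avg	16	1265.46	1174.12	1270.33
avg	32	624.73	666.91	640.63
avg	64	379.08	376.06	366.84
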