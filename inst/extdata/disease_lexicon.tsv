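# demonstration disease lexicon: surface form <TAB> concept id (synthetic demo resource)
melanoma	D008545
breast cancer	D001943
lung cancer	D008175
colorectal cancer	D015179
thyroid cancer	D013964
leukemia	D007938
lymphoma	D008223
glioblastoma	D005909
neurofibromatosis	D009456
retinoblastoma	D012175
pancreatic cancer	D010190
ovarian cancer	D010051
prostate cancer	D011471
gastric cancer	D013274
hepatocellular carcinoma	D006528
renal cell carcinoma	D002292
multiple myeloma	D009101
osteosarcoma	D012516
medulloblastoma	D008527
sarcoma	D012509
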