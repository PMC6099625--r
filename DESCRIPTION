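Package: corpusBalance
Title: Static Load Balancing for Parallel Biomedical Text-Mining Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infrastructure for distributing document-level biomedical
    text-mining jobs across parallel workers. Reads and writes the PubTator
    annotation exchange format and extracts documents from JATS/NXML full-text
    XML; models per-file processing cost as an affine function of character
    count; implements three static scheduling strategies (modulo/random,
    serpentine round-robin, and a longest-processing-time greedy) together
    with the load-balancing-efficiency (LBE) statistic, makespan accounting
    and a brute-force optimal-makespan oracle for small instances; runs
    lightweight demonstration named-entity annotators over an assigned corpus
    on serial or local multi-process backends; and provides a pure-arithmetic
    scheduling simulator for strategy comparisons on a single machine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, parallel, xml2
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
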