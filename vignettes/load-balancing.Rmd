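---
title: "Static load balancing for document-level text mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static load balancing for document-level text mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corpusBalance)
```

# The problem

Document-level named-entity recognition over the biomedical literature is
parallel at the file level: articles are independent, so a corpus can be
partitioned across workers that never communicate while processing. Two
empirical facts shape how that partition should be chosen:

1. **Cost scales with text length, not article count.** Per-file processing
   time is well approximated by an affine function of character count,
   `t(s) = a + b·s`. Article lengths are heavily skewed (full texts can be
   orders of magnitude longer than abstracts), so equal *file counts* per
   worker produce very unequal *work* per worker.
2. **Initialisation is expensive.** Real NER tools load multi-gigabyte
   dictionaries at startup, so each worker pays a large one-time cost per
   run. This both fixes the unit of work at the file (not the sentence) and
   caps the useful degree of parallelism: once per-worker initialisation
   dominates, adding workers stops reducing wall-clock time.

Because all assignment decisions are made before any work starts (static
scheduling), the whole run finishes when its slowest worker finishes. The
quantity to minimise is the **makespan** (maximum per-worker time); the
quality statistic is the **load-balancing efficiency**

$$\mathrm{LBE} = \mathrm{AET} / \mathrm{MET},$$

average execution time over maximum execution time. LBE is 1 exactly when
all workers finish together, is invariant to a common positive rescaling of
times, and decreases towards `1/n` as one worker comes to dominate.

# The three strategies

Given files with costs (predicted seconds, or raw character counts under
the default identity model):

- **Modulo** (`assignModulo`): file at 0-based list position `P` goes to
  rank `P mod n`. Size-blind; with an arbitrarily ordered file list this is
  effectively random distribution, and it is the baseline the size-aware
  strategies are measured against. A seeded shuffle reproduces the
  "arbitrary directory order" situation deterministically.
- **Serpentine round-robin** (`assignRoundRobin`): sort by cost descending,
  deal in alternating passes `0,1,…,n−1` then `n−1,…,1,0`. Every rank gets
  an (almost) equal number of files, and pairing each large file with small
  ones keeps totals roughly level — until the size distribution becomes so
  skewed that one file outweighs everyone else's total.
- **Short-Board** (`assignShortBoard`): sort by cost descending and
  dispatch each file to the rank with the smallest current cumulative
  cost. This is the classic longest-processing-time (LPT) greedy for
  makespan minimisation on identical machines; its makespan is at most
  `4/3 − 1/(3n)` times the optimum. The name is the "shortest stave of the
  barrel" metaphor: the least-loaded worker is topped up first.

Two interpretation choices the strategies depend on were genuinely open and
are fixed as follows. *Load* in the greedy strategy means cumulative
predicted cost, not file count — the strategy exists precisely because file
counts are the wrong measure. Under the default identity model (cost = raw
size, intercept 0) this coincides with cumulative size; with a fitted model
the intercept adds a per-file overhead and the two differ — the model used
for scheduling is an explicit argument, so either reading is available.
Second, ties (equal costs, equal loads) are broken deterministically — by
file id ascending and lowest rank respectively — purely so that assignments
are reproducible; no ordering claim is attached. The serpentine deal starts
left-to-right at rank 0 by convention.

# Annotation format and offsets

The PubTator exchange format is line-oriented: a title line
`<id>|t|<title>`, an abstract line `<id>|a|<body>`, then tab-separated
annotation lines (id, start, end, mention, type, optional concept id),
blocks separated by blank lines. Offsets are 0-based, end-exclusive, and
counted in decoded characters — the same unit the workload model uses —
over the *composite text*. The format itself never states what separates
title from abstract in the offset arithmetic; this package fixes the
composite text as title + exactly one space + body (title alone when the
body is empty), which matches common practice of counting one character
between the two fields and keeps mentions readable. Newlines inside
titles or abstracts cannot be represented in a line-oriented format and
are replaced by single spaces at ingest.

The reader validates every annotation (offsets in range, mention equal to
the indexed substring) and is strict by default — a malformed record aborts
with its line number — because scheduling downstream relies on trustworthy
sizes; a lenient mode skips bad records with a warning for salvage work.
Written output always emits six tab-separated fields (empty concept id
allowed) so consumers can rely on a fixed arity; the reader accepts five or
six. Read after write is the identity, property-tested on generated
corpora. Full-text JATS/NXML input is flattened to the same document shape;
whether full text should *replace* or *follow* the abstract in the `a`
field is unspecified upstream, and this package concatenates abstract then
body paragraphs under the `includeFullText` flag.

# The workload model

`fitTimeModel` is unweighted ordinary least squares of seconds on size —
unweighted because the motivating calibration data are a handful of points
with no variance information. The model records its size unit (`chars` or
`MB`, converted at 1 MB = 10⁶ characters) so MB-scale fits serve
character-scale predictions. On the bundled serial benchmark (total time
for 1, 2, 4, 8 MB inputs) the fit is ≈ 848 + 1128·MB seconds with all
fitting-point residuals under 15 %. A fitted intercept can come out
slightly negative on noisy data; the class warns rather than refuses, and
schedulers are unaffected (ordering decisions are invariant to the
uniform affine transform except through the intercept, which defaults
to 0).

# Synthetic corpora

`generateCorpus` draws i.i.d. file sizes from one of four distributions and
is the package's study-condition generator; its defaults are fixed once:

| distribution | defaults | emulates |
|---|---|---|
| uniform | min 100, max 10 000 chars | benign, narrow spread |
| lognormal | meanlog log(5000), sdlog 1 | abstract-dominated corpora |
| pareto | xmin 1000, tail index α 1.5 | full-text skew: few huge files |
| twopoint | 500 / 50 000, 5 % large | worst-case bimodality |

The Pareto tail index 1.5 gives a finite-mean but very heavy tail — the
"some files are extremely long while many others are short" regime where
round-robin's equal-count deal fails. `materializeCorpus` writes files of
exactly the drawn sizes; its `"biomedical"` vocabulary salts the random
text with gene/disease/mutation mentions so the demonstration annotators
have something to find, which is what the end-to-end correctness tests use.
What the generator deliberately does **not** emulate: correlation between a
file's length and its entity density, per-plugin cost differences, and any
I/O or memory contention. Passing tests therefore demonstrate scheduling
and format correctness, not NER quality or hardware-level performance on
real corpora.

# Engine, plugins, backends

Annotators follow a two-step contract (`init()` once per worker,
`annotate(doc, state)` per document) because that is the cost structure of
real tools. The engine is a static scatter–gather: the assignment is
computed once, workers process only their own files and never communicate,
outputs are gathered afterwards. Backends are `serial` (all ranks
in-process, timing attribution preserved) and `local` (one forked OS
process per rank). A distributed message-passing backend is out of scope
for this package; the plan-file format (`writePlan`: rank, file id, cost
per line) is the hand-off point for external launchers that implement the
same contract. Per-plugin `maxProcsPerNode` caps — real tools are
memory-bound to a handful of processes per node — are enforced as a
warning, since physical node placement is not observable portably.

A file that fails (unreadable, malformed) is isolated: its failure is
logged, every other file is still processed, and strict mode escalates at
the end. Timing uses the elapsed-time clock; logged wall-clock values are
never asserted in tests, only structural properties (every (file, plugin)
pair timed exactly once, one init per plugin per worker).

The central correctness property is that the annotation set — as a set of
(doc id, start, end, type, concept) tuples — is invariant to backend,
strategy and worker count. The demonstration taggers (a regex mutation
tagger and two dictionary taggers with ~20-entry bundled demo lexicons) are
pure functions of the document, which is what makes that invariance
testable end to end.

# Simulator and numerical choices

`simulateRun` computes a strategy's assignment from model-predicted costs
and sets each rank's time to `initCost` plus its group's predicted total —
pure arithmetic, no annotators. With zero init cost and the identity model
its MET equals `makespan` exactly (tested). As init cost grows, LBE tends
to 1 while MET plateaus at the init cost: balanced but not faster, the
diminishing-returns regime. `compareStrategies` averages MET/AET/LBE over
seeds, where seeds move only the modulo shuffle and (when a generator
function is supplied) the corpus draw.

The brute-force `optimalMakespan` oracle enumerates rank choices
depth-first in descending-cost order with two prunings (bound on the
incumbent; at most one empty rank offered per file, since empty ranks are
interchangeable) and is capped at 14 files / 4 ranks — 4⁴ ≈ 2.7 × 10⁸
leaves worst case before pruning, milliseconds in practice — because it is
a test oracle, not a scheduler.

Problem sizes in the test suite were chosen to make the statistical
properties stable under fixed seeds while keeping the default run fast:
500 random instances for the LPT bound, 50–200 seeds for strategy-ranking
means, 200 generated corpora for the format round-trip, a 50-document
corpus for backend-equivalence runs. Makespan monotonicity in the worker
count is asserted for the two size-aware strategies only: the modulo deal
is size-blind and provably non-monotone (sizes 1,1,10,1,1,10 give makespan
12 on two ranks but 20 on three, where both big files land on one rank).

# Known limitations

- Annotation quality is a non-goal; the demonstration taggers exist to
  exercise the pipeline, not to recognise entities well.
- One cost model serves all plugins in a run. Real tools have very
  different slopes; separate `WorkloadModel`s per plugin are supported for
  reporting, but no joint multi-plugin schedule is computed.
- The simulator models neither memory contention nor I/O, so simulated
  times are comparative, not predictive of wall-clock values on any
  particular machine.
- Character counts assume decoded text; byte-oriented size on disk will
  disagree for non-ASCII corpora, deliberately.
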