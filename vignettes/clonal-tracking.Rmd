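---
title: "Methods: clonal tracking from expressed RNA barcodes"
author: "clonetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal tracking from expressed RNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

# The assay and its model

Lentiviral cellular barcoding marks each transduced hematopoietic stem cell
with a unique semi-random DNA sequence placed in the 3' end of an eGFP
transcript. Because the barcode is *expressed*, clone identities can be read
not only from nucleated cells but also from anucleate platelets and
erythrocytes, whose residual mRNA suffices for amplicon sequencing. A clone
is the set of cells sharing one barcode; tracking barcode abundances across
peripheral-blood lineages (platelets P, erythroid E, myeloid M, B cells B)
and weeks yields a clone × lineage × time table of percentage
contributions, and single-cell RNA-seq of bone-marrow stem/progenitor
populations links each clone to the transcriptomes of its cells.

`clonetrace` implements this analysis end to end, together with a
synthetic-data module that generates every input with known ground truth.
The simulators are first-class, tested code: all quantitative guarantees of
the pipeline are demonstrated as closed loops between generator and
analyzer.

# Barcode extraction

Amplicon reads have the layout `9-nt multiplex tag + 22-nt constant forward
anchor (eGFP 3' end) + barcode + reverse primer site`. Extraction:

1. **Demultiplexing** is an exact match of the first nine bases against the
   tag map. The assay gives no evidence for tag error tolerance, so
   tolerant tag matching is deliberately not offered; non-matching reads go
   to an `undetermined` bin and the partition is exhaustive.
2. **Anchor search** accepts the anchor at Hamming distance ≤ 1. The
   published tolerance "distance = 1 (± 1 nucleotide)" is ambiguous between
   a positional shift and an indel; we interpret it as ≤ 1 substitution
   *and* a start-position shift of ± 1 (both caps configurable via
   `anchor_spec()`). Substitution-only error is also what motivates the
   default read simulator; indel injection is out of scope. Among
   qualifying window positions the smallest distance wins, ties to the
   leftmost position.
3. **Assignment** takes the `L` bases after the anchor. The `exact` policy
   requires a perfect library match. The `correct1` policy additionally
   assigns a read to the unique library barcode within Hamming distance 1;
   this is only unambiguous when the library's minimum pairwise distance is
   ≥ 3, which the function verifies and otherwise refuses — it never
   silently degrades. Internally the policy is a hash lookup over all
   single-substitution neighborhoods, which are provably disjoint at
   distance ≥ 3.
4. **Counting** zeroes per-sample barcode counts below `min_count`
   (default 3) and removes the known noninformative barcode *before* any
   normalization, so it never inflates denominators. The published wording
   is ambiguous between "count > 3" and "counts below 3 ignored"; the
   default keeps a count of exactly 3, and `min_count` is configurable.
   The same threshold governs per-cell assignment.

The confidence behind small read-count thresholds is the chance-collision
probability `(1/library size)^reads`: for 800 barcodes and 4 reads,
2.44·10⁻¹².

# Quantification and diversity

Counts are normalized per 1000 and as fractions of the sample total;
zero-total samples are flagged and dropped, never divided. The **dominant
set** is the minimal descending-abundance prefix whose cumulative fraction
reaches the threshold (default 0.90), with boundary ties resolved by
barcode identifier and an absolute tolerance of 1e-9 against floating-point
round-off at exact boundaries (ten equal clones at threshold 0.90 give
k = 9 exactly). A strict-greater variant is available by flag. The default
scope pools all of a mouse's blood samples before ranking, matching the
practice of ranking barcodes across blood populations per mouse;
`dominant_sets(scope =)` gives per-sample scoping.

Chimerism correction multiplies a clone's within-eGFP⁺ lineage fraction by
the lineage's eGFP⁺ chimerism, re-expressing it as a share of the whole
lineage. The classification threshold (below) is applied *before*
correction by default — on within-label fractions — because the detection
limit was established on pure labeled material; this choice is
flag-controlled by correcting first if desired.

Replicate concordance is the ordinary least-squares R² of one replicate on
the other over the union of barcodes (absent = 0); with fewer than three
barcodes non-zero in both replicates it is reported as undefined rather
than a misleading number. Pearson correlation between lineage/time
compositions is computed on raw fractional contributions without log
transform or pseudocount — no transform is part of the correlation
definition; a log10 display scale with pseudocount 0.001 is purely a
plotting convention and is not baked into the statistic. Zero-variance
compositions yield `NA` rather than an error.

Diversity uses the Shannon index with the natural logarithm,
H = −Σ pᵢ ln pᵢ with 0·ln 0 = 0, which is the only reading consistent with
the Shannon count Sh = e^H and its uniform-case identity Sh = s. The
directed overlap statistic |A\B| / |A∪B| is implemented verbatim as the
"fraction of clones missed" measure on presence/absence sets; because it is
asymmetric by construction, the symmetric Jaccard distance is provided as a
separately named companion (`jaccard_distance()`) to avoid silent
confusion. The two directed statistics sum to the symmetric distance, a
relation the tests assert.

# Clone classification and dynamics

A lineage letter is credited to a clone when its contribution exceeds
**0.089%** — the empirical detection limit from the calibration mixtures,
1/1121 of the ten-clone design — at **2 consecutive** time points. Both
parameters live in `classification_rule()`. The published material states
"2 consecutive time points" in one place and "2 time points" in another;
the default requires consecutiveness and `require_consecutive = FALSE`
relaxes it (the same flag governs the repurposing/activation windows).
Comparisons are strict on both sides: exactly 0.089% qualifies neither as
present nor as silent — a documented boundary. Labels are assembled in
canonical P, E, M, B order; clones qualifying nowhere are reported as
`unclassified`, never dropped.

Across a perturbation (acute platelet depletion):

* **repurposed** — classified PEMB over the pre-window *and* myeloid
  contribution < 0.089% at *every* post-window time point;
* **activated** — below 0.089% (or absent) in a lineage at every
  pre-window time point *and* above it at the rule's required number of
  post-window points;
* **lost** — classified pre, unclassified post: a bookkeeping extension of
  ours, clearly marked as such;
* **stable** / **unclassified** otherwise.

Repurposed and activated are mutually exclusive by construction (a PEMB
clone is above threshold in every lineage at the pre time points, which
violates the activation pre-silence condition); the tests assert this as a
property over randomized series.

# The synthetic-data generators

The generators define the study conditions under which the pipeline's
guarantees are demonstrated.

**Library**: rejection sampling of uniform random sequences with a pairwise
Hamming floor (default length 32, distance ≥ 3; 800 barcodes by default
downstream, matching the collision arithmetic). An infeasible parameter
combination fails explicitly after a bounded attempt budget. The known
noninformative sequence is 43 nt; appending it requires a 43-nt library so
the uniform-length invariant holds.

**Reads**: multinomial identity draws from the mixture fractions;
substitutions injected i.i.d. per base (exactly — hit positions are sampled
globally over all bases without replacement). Error rates around 1% emulate
the slightly elevated barcode detection error of cDNA relative to genomic
DNA; indels are intentionally absent (see anchor discussion).

**Time course** (defaults; chosen once as realistic for this assay):
200 active clones drawn from a 13-class lineage-output palette dominated by
multipotent PEMB clones (35%), sampling weeks 12/20/28/30, perturbation
optional at week 28. Per-clone base output sizes are uniform on [2, 10]: at
these cohort sizes every active clone's share of a lineage stays well above
the 0.089% detection limit (typically 0.3–3%, mirroring the reported
0.1–10% per-clone range), so noiseless label recovery is exact by
construction and recovery under noise degrades gracefully rather than at a
cliff. Noise is multiplicative log-normal per (clone, lineage, week) with
CV 0.2 and mean 1, followed by renormalization of each (lineage, week)
column to 100% — preserving the compositional structure of the data. The
repurposed fraction of PEMB clones defaults to 0.7 (reported range
57–81%); a silent pool of 20% of the cohort provides the substrate for
activation (the published material quantifies activated clones but not the
latent pool size, so the pool is an explicit config field, `n_silent`),
of which 75% activate into myeloid or platelets. Repurposed clones' myeloid
output is set to zero after the perturbation (below any threshold even
after renormalization); activated clones receive sizes from the same
distribution as founding clones.

**Single cells**: per-population cell numbers (default 200/150/150 for
LT-HSC/MkP/CFU-E, totalling 500), log-normal depth centred on 1M reads/cell,
Beta(2, 38) mitochondrial fraction (mean 5%), barcode capture dropout 0.1
(emulating >90% recovery), barcode read counts negative-binomial shifted by
a minimum of 3 (capture, when it happens, yields at least a few reads), and
negative-binomial gene counts with log-normal gene means scaled by the
cell's depth. Gene counts model overdispersed expression only — no cell-type
structure, batch effects, or zero-inflation beyond the negative binomial.

**What passing tests do and do not show.** The generators produce
substitution-only errors, independent reads (no PCR amplification bias or
jackpotting), clean compositional noise and a fixed class palette. Passing
the closed loops therefore demonstrates the *correctness of the
algorithms* under the stated statistical model, not robustness to every
artifact of real sequencing data (chimeric reads, index hopping,
amplification bias, contamination). The thresholds themselves (0.089%,
min_count 3, QC cuts) are taken from the assay's published calibration, not
fitted to the simulations.

# Numerical choices and degenerate inputs

* Seeds are explicit arguments to every generator; fixed seed implies
  bit-identical output, which the tests and the demonstration pipeline
  (`run_pipeline()`, byte-identical reruns) assert.
* Shannon input must sum to 1 within 1e-6; zeros are skipped by the limit
  convention.
* Dominant-set boundary tolerance 1e-9 (absolute, on cumulative
  fractions).
* Empty read sets, empty samples, zero-total columns, zero-variance
  compositions, both-empty clone sets and anchor-longer-than-read all have
  defined behavior (empty results, flagged warnings, `NA`, or explicit
  errors naming the problem) rather than silent propagation.
* QC comparisons are strict (`> 50000` reads, `< 0.10` mito), matching the
  published exclusion wording; boundary cells are excluded.
* Doublet policy for cells: if a second barcode also reaches `min_count`,
  the cell is flagged multi-barcode and left unassigned. The assay's
  publication record is silent on multi-barcode cells; this conservative
  policy is our design decision, justified by the collision probability
  making chance co-occurrence negligible, so concordant multi-barcode
  signal most plausibly indicates a doublet.
* Pseudo-bulk grouping defaults to user-supplied keys; the recommended key
  is mouse × clone-status, preserving animals as biological replicates.
  Groups below `min_cells` are flagged, not dropped.

# Problem sizes

The shipped tests and the acceptance script use an 800-barcode library with
1e5-read channels, 200-clone (+40 silent) time courses, and a 500-cell ×
2000-gene single-cell cohort — large enough for the binomial/multinomial
error bounds asserted in the tests to be meaningful, while keeping a full
run in well under a minute on one CPU.

# Known limitations

* No UMI handling (the assay has none) and no reverse-complement read
  search (amplicon orientation is fixed by the primer design; available by
  pre-processing if ever needed).
* No indel-tolerant barcode matching; libraries with pairwise distance < 3
  can only use the `exact` policy.
* No statistical testing of class-contribution differences, no
  normalization/clustering/differential expression for the single-cell
  matrices — pseudo-bulk tables are emitted for established external tools.
* The generalized linear model display of calibration concordance is
  reduced to ordinary least-squares R²; that is the only regression
  quantity the pipeline consumes.
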