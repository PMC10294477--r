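# clonetrace

Clonal tracking of nucleate **and anucleate** blood lineages from expressed
RNA barcodes.

Platelets and erythrocytes carry no nuclear DNA, so DNA-based cellular
barcoding cannot read clone identities from them. When hematopoietic stem
cells are labeled with a lentiviral library whose barcode sits in the 3' end
of an eGFP transcript, the barcode is expressed as mRNA and can be amplified
and sequenced from every peripheral-blood lineage — platelets (P), erythroid
cells (E), myeloid cells (M) and B cells (B) — as well as from single
bone-marrow stem and progenitor cells. `clonetrace` implements the full
analysis around that assay for researchers studying clonal hematopoiesis:

* **Synthetic data** with known ground truth for every pipeline input:
  semi-random barcode libraries with a minimum pairwise Hamming distance,
  calibration clone mixtures, amplicon reads with per-base substitution
  errors, perturbed clonal time courses, and barcoded single cells.
* **Barcode extraction**: anchored search for the constant eGFP primer
  region at Hamming distance ≤ 1 (± 1 position), barcode assignment by exact
  match or unique single-substitution correction, 9-nt tag demultiplexing,
  and counting with a minimum read-count filter (counts below 3 ignored) and
  exclusion of the known noninformative barcode.
* **Quantification**: per-1000 normalization, dominant-set selection (the
  top barcodes jointly covering ≥ 90% of abundance), chimerism correction,
  technical-replicate concordance (R²), relative measurement error
  δ = |(υ_A − υ_E)/υ_E|·100%, and Pearson correlation matrices between
  lineage/time clone compositions.
* **Diversity**: Shannon index H = −Σ pᵢ ln pᵢ, Shannon count Sh = e^H (the
  effective number of equally contributing clones), and the directed
  set-overlap statistic J_dist = |A\B| / |A∪B| used to quantify clones
  missed between compartments.
* **Clone dynamics**: lineage-output classification (a lineage letter is
  credited when the clone contributes > 0.089% at 2 consecutive time
  points), detection of *repurposed* multipotent clones (PEMB before an
  acute platelet depletion, myeloid output < 0.089% at every time point
  after it) and of *activated* clones (silent before, above threshold
  after), and per-class cumulative lineage output.
* **Single-cell linking**: QC (> 50,000 reads and < 10% mitochondrial
  fraction), per-cell barcode assignment with a doublet guard justified by
  the chance-collision probability (1/800)⁴ = 2.44·10⁻¹², annotation of
  cells with their clone's blood classification, and pseudo-bulk
  aggregation for downstream differential expression.

## Worked example

Simulate the ten-clone calibration mixture (ratios
1:10:10:50:100:100:200:200:200:250), sequence it with 1% substitution error,
and recover the design:

```r
library(clonetrace)

lib <- generate_barcode_library(800, length = 32, min_dist = 3, seed = 1)
mix <- simulate_mixture(lib, c(1, 10, 10, 50, 100, 100, 200, 200, 200, 250))
round(100 * min(mix$fraction), 3)
#> [1] 0.089        # the smallest clone: 1/1121 of the mix

reads <- simulate_amplicon_reads(mix, 50000, sub_rate = 0.01,
                                 tag = "AAACCCGGG", seed = 2)
counts <- extract_counts(reads, c(AAACCCGGG = "calib"), lib,
                         policy = "correct1")
ab <- normalize_abundance(counts)
round(sort(ab$per_1000[, "calib"], decreasing = TRUE), 1)
#> BC0010 BC0009 BC0008 BC0007 BC0006 BC0005 BC0004 BC0002 BC0003 BC0001
#>  223.0  181.9  177.6  174.9   90.7   90.2   43.2    9.3    8.3    0.9

diversity_summary(ab$fraction[, "calib"])
#>       s     H    Sh
#> 1    10  1.92  6.80
```

The per-1000 values track the designed ratios (223 ≈ 250/1121·1000), the
0.089% clone is recovered at 0.9 per 1000, and the skew of the design pulls
the effective clone number (Shannon count) down from 10 observed barcodes
to 6.8.

Classifying clone dynamics across a simulated platelet depletion at week
28:

```r
sim <- simulate_clonal_timecourse(timecourse_config(perturbation_time = 28,
                                                    seed = 3))
dyn <- classify_dynamics(sim$ts, pre_window = c(12, 20),
                         post_window = c(28, 30))
table(dyn$status)
#>    activated   repurposed       stable unclassified
#>           30           57          143           10
```

Repurposed clones are multipotent (PEMB) clones whose myeloid output fell
below the 0.089% detection limit after the depletion; activated clones rose
from silence into myeloid or platelet output.

`run_pipeline(out_dir, seed)` chains the whole
simulate → extract → quantify → classify path and writes every table plus a
JSON run summary; reruns with the same seed reproduce the outputs byte for
byte.

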