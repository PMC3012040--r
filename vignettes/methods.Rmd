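---
title: "Methods: from bisulfite clone sequences to methylation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bisulfite clone sequences to methylation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methclones)
```

## The measurement model

Bisulfite treatment deaminates unmethylated cytosine to uracil, which is
read as thymine after PCR; 5-methylcytosine is protected and stays
cytosine. A sequenced clone of a treated molecule therefore differs from
its genomic reference in a characteristic, *directional* way: reference C
positions read T wherever the cytosine was unmethylated (or, outside CpG
context, almost always), and read C where it was methylated or where the
chemistry failed. Everything in this package follows from taking that
asymmetry seriously at each step.

Three nuisance processes stand between raw sequences and a methylation
profile:

1. **Orientation.** Sequencer output may be reversed, complemented or
   reverse-complemented relative to the reference.
2. **Incomplete conversion.** Unconverted unmethylated Cs masquerade as
   methylation.
3. **Sequencing error.** Miscalled bases corrupt both identity and
   methylation calls.

## Alignment and orientation control

Clones are aligned to the reference with a global affine-gap
Needleman–Wunsch algorithm (Gotoh three-state recursion, compiled code).
The substitution scheme scores clone T against reference C as
`bisulfite_TC` (default: the full match score), while clone C against
reference T remains an ordinary mismatch — conversion happens on the clone
strand only, so the tolerance must be directional. `N` scores 0 against
everything; other IUPAC ambiguity codes score a match when their base sets
intersect. Defaults are match +1, mismatch −1, gap open −2, gap extend −1
(a gap of length L costs `open + (L−1)·extend`). No published penalty set
exists for this problem class, so the scheme is fully configurable and is
echoed into every run's provenance record; gap-penalty sensitivity is a
known property of bisulfite alignments, especially around runs of Ns.

Orientation control scores **four** candidates — the clone as given plus
its reverse, complement and reverse-complement — and keeps the best. A
correctly oriented clone is thus never transformed; the three wrong
orientations are only ever chosen when they genuinely score higher. Ties
resolve deterministically in the order identity, reverse, complement,
reverse-complement, and traceback prefers diagonal over a gap in the clone
over a gap in the reference, so equal-score alignments are reproducible.
When all four candidates score identically at or below a floor (default 0)
the clone is flagged unalignable instead of being silently returned.

Reported spans trim terminal gap columns: `ref_start..ref_end` is the
1-based closed reference interval the clone actually covers, on the
forward strand.

## Quality control

Two statistics are computed per clone:

* **Conversion ratio** = unconverted Cs at non-CpG reference positions ÷
  all non-CpG reference Cs covered by the alignment. CpG-ness is decided
  on the *reference* forward strand (a reference C is CpG iff followed by
  G), because the clone's own dinucleotide context is distorted by
  conversion. Gap and clone-N columns are excluded from numerator and
  denominator. This is a treatment **failure** rate, so reports also carry
  `conversion_success = 1 − ratio` to prevent misreading. A clone covering
  no non-CpG C gets a missing ratio and fails its gate explicitly.
* **Identity rate** = matches ÷ (matches + mismatches) from a
  Smith–Waterman local alignment, tallied only over columns where the
  reference base is A, G or T. Excluding reference-C columns removes the
  bisulfite signal from the identity estimate, so the rate measures
  sequencing fidelity, not methylation.

Default gates — conversion ratio ≤ 0.1, identity ≥ 0.8 — are ordinary
practice for clone-level bisulfite work but carry no special authority;
both are parameters, and every failing clone names the gate(s) it
violated.

## The methylation dataset

Calling walks the alignment columns at each reference CpG position: clone
C → methylated (1), clone T → unmethylated (0), anything else — gap, N, or
a non-C/T base — is **missing** (NA), because a G or A at a CpG column
evidences sequencing error, not a methylation state. Positions outside the
clone's span are missing. Missing is a first-class third state throughout:
summaries exclude it from denominators, correlations and distances use
pairwise-complete observations, and the Fisher tables exclude it listwise
per site. Orientation is normalized *before* calling, so calls are always
made on the forward-oriented clone and no reverse-strand (GpC) logic is
needed.

The container (`meth_set`) holds clone ids, CpG positions, the ternary
matrix and the spans; it serializes to a self-describing, versioned JSON
document plus a TSV matrix export, both of which round-trip exactly.

## Statistics

* **Co-occurrence.** Two readings of "agreement between two sites across
  clones" are exposed, because the informal field usage covers both: the
  *phi coefficient* (Pearson correlation of the two binary columns over
  pairwise-complete clones) and the *shared fraction* (1 − normalized
  Hamming distance). Pairs with fewer than two complete clones or zero
  variance are missing-flagged, never NaN.
* **Fisher per-site test.** Two-sided exact p on the 2×2 group ×
  state table, two-sidedness by summing hypergeometric point
  probabilities ≤ that of the observed table. Zero-margin tables are
  degenerate: reported p = 1 with a flag rather than tested. No
  multiple-testing correction is applied by default — per-site p-values
  are exploratory here — but Benjamini–Hochberg adjustment is available
  behind a flag.
* **Mann–Whitney set test.** The sampling unit is the per-site percent
  methylation, compared across sites between the two clone sets (a
  per-clone unit is available behind a flag). For combined n ≤ 20 the
  p-value is exact by full enumeration of group assignments, which remains
  valid under the heavy ties binary percentages produce; beyond that a
  normal approximation with tie correction (no continuity correction) is
  used.
* **Biclustering.** Rows and columns are clustered independently with
  agglomerative linkage (default complete) on the normalized Hamming
  distance — the natural metric for binary patterns, unlike Euclidean
  distance on indicator codes. Clustering refuses to run when any pair
  shares no comparable position, rather than guessing. Column clustering
  deliberately ignores genomic ordering.
* **Correspondence analysis.** Standard chi-square decomposition of the
  raw 0/1 indicator matrix: `P = X/n`, masses `r`, `c`, SVD of
  `D_r^{-1/2}(P − rc^T)D_c^{-1/2}`; principal inertias `λ_k = σ_k²` sum to
  `χ²/n`; principal coordinates are the mass-rescaled singular vectors
  scaled by σ. The matrix is *not* doubled and duplicate clones are
  *retained* — identical clones carry mass and should pull their sites, as
  the four-clone demonstration example shows. Missing calls are handled
  before decomposition, by default by omitting incomplete clones (with a
  warning); zero-filling is available when dropping rows is worse than
  biasing them.

## Numerical choices

* Binarization of continuous inputs uses a ≥ threshold rule (ties → 1).
* CA dimensions with `λ < 1e−12 · λ_max` are treated as numerically null;
  a table with independence structure (everything below 1e−12) returns
  zero total inertia and no dimensions rather than noise axes.
* Exact-test enumerations use a 1e−9 slack when comparing statistic
  distances and the conventional `(1 + 1e−7)` slack when comparing
  hypergeometric point masses, so floating-point ties break toward
  inclusion.
* Leaf order and alignment traceback ties follow fixed, documented orders;
  repeated runs are byte-identical, which the pipeline manifest checksums
  make testable.

## The simulator, and what passing tests mean

`sim_config()`/`simulate_experiment()` generate a reference whose only
cytosines are planted — CG dinucleotides at requested positions and a
chosen number of non-CpG Cs (never followed by G) — over an A/G/T
background, then derive clones by applying the bisulfite rule to a known
methylation pattern, planting conversion failures at a configured
probability, substitution errors at a configured rate, optional coverage
windows, and orientation transforms. Every random draw is recorded in a
ground-truth object, and one seeded stream makes output byte-reproducible.

The defaults mirror the demonstration geometry: a 100 bp reference with
five CpG sites at positions 7, 32, 48, 55 and 73, four clones, ten non-CpG
cytosines, noise off. Property tests use sizes chosen for tight
ground-truth arithmetic rather than realism: 200 clones of ~120 bp at 1%
substitution error for orientation recovery, 50 clones × 20 non-CpG Cs for
conversion-ratio recovery at failure probabilities {0, 0.05, 0.2}, random
matrices up to 8×8 against a first-principles χ² oracle for CA, all 2×2
tables with total ≤ 30 for Fisher, and combined n ≤ 12 for Mann–Whitney
enumeration.

What the simulator does **not** model bounds what green tests can say
about real data: no chromatogram-level base-calling uncertainty, no
quality scores, no PCR duplicates or chimeras, no indel sequencing errors
(substitutions only), no strand-specific conversion chemistry differences,
and uniform error rates along the read. A clone set that passes this
package's QC can still carry artifacts these tests cannot see.

## Known limitations

* Single reference, single locus; no multiple sequence alignment and no
  genome-scale scans. High-throughput short-read data is out of scope.
* Non-CpG (CHG/CHH) methylation is not called.
* Incomplete conversion is gated on, not modelled in downstream
  statistics.
* The original clone-analysis tools this package parallels never
  published their substitution matrices or gap penalties, so score-level
  agreement with them is not claimed anywhere; where behaviour is
  compared, it is compared on called matrices and statistics.
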