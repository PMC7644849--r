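---
title: "Promoter motif mapping with chromatin filtering: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter motif mapping with chromatin filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promscan)
```

# The procedure

`promscan` implements a promoter regulatory-element mapping procedure
and its companion quantification arithmetic. The pipeline has four
stages:

1. **Promoter extraction.** For each gene, the 10-kb window
   immediately 5′ of the start codon on the gene's strand. The window
   is anchored at the *start codon*, not the transcription start site:
   that is the stated definition of the procedure this package
   reproduces, and we keep it even though TSS-anchored promoters are
   the more common convention. The start-codon base itself is
   excluded; windows running off a chromosome edge are truncated and
   flagged rather than rejected (synthetic chromosomes are short).
2. **PWM scanning.** Every offset, both strands. A site is *bona
   fide* iff its min–max relative score strictly exceeds 0.89.
3. **Chromatin filtering.** Histone-mark state and ChIP-seq cluster
   evidence, two independent tri-state flags per hit
   (`untested`/`pass`/`fail`).
4. **Comparison.** Surviving hits reduce to per-gene TF sets;
   2–3-way Venn partitions and per-TF gene lists are computed from
   those sets.

# Scoring model and its assumptions

The PWM is the log2-odds of a pseudocount-smoothed column probability
against a background model. Background and pseudocount are not
dictated by the source procedure, so the defaults are the most
reproducible choices: **uniform background** (0.25 each) and
**pseudocount 1**, both arguments of `pfm_to_pwm()`. A GC-aware
background would need a genome composition estimate and would change
scores by fractions of a percent for the strongly peaked motifs the
fixtures use.

"Potential match" is interpreted as the min–max normalised score
`(S − S_min)/(S_max − S_min)` — the only widely used PWM statistic
reported as a percentage match to a motif. Two boundary conventions
are fixed deliberately:

* the threshold comparison is **strict** (`> 0.89`), matching
  "higher than 89%";
* a degenerate, fully uniform motif (where `S_max = S_min`) scores 1
  for every k-mer, so it matches everywhere rather than nowhere.

Consensus ties break alphabetically (A < C < G < T) for determinism.
**Binding efficiency** is defined as
`relative_score(x) / relative_score(consensus)`; whenever column
maxima are unique the denominator is exactly 1 and the efficiency
equals the relative score. Whether the original "binding efficiency"
was a probability ratio instead is not stated anywhere; the
normalised-score ratio is the documented choice. Ambiguous bases are
rejected by default (`ambiguous = "reject"`): synthetic fixtures never
emit them, and silent handling of N runs in real genomes hides data
problems. The alternative `"background"` policy scores an N at the
column's background-expected value.

Both strands are scanned. The source procedure is silent on this;
double-stranded scanning is the default of the scanner tradition it
belongs to, and a minus-strand site is reported with the offset of its
leftmost promoter base and the motif-strand k-mer.

# Chromatin and evidence filters

Three knobs of the filtering rules are genuinely unspecified and are
therefore explicit `chromatin_config()` fields, surfaced in the run
log of every pipeline report:

* **"near"** a motif = ±1000 bp (`window`). Promoter histone marks
  have roughly kilobase resolution; the value is an assumption, not a
  measurement.
* **presence of H3K4me3, H3K36me3, H3K27ac** is read as *any-of*
  (`activating_rule = "any"`); the three marks rarely co-occur with
  equal strength at one locus, so all-of would empty most fixtures.
  `"all"` is selectable.
* **absent ChIP-seq cluster** ⇒ excluded
  (`missing_cluster_policy = "exclude"`): the evidence step exists to
  *exclude* sites lacking binding evidence, so no evidence means
  exclusion, equivalent to score 0.

The evidence rule itself is sharp: clusters scoring `< 500` of 1000
exclude a site, so 500 passes and 499 fails; cluster labels match the
hit's TF name case-insensitively (`tf_name_matching = "exact"`), with
`"ignore"` available for unlabelled aggregate tracks. The two filters
commute (each writes only its own flag), which the test suite asserts.

The Venn comparison runs on *surviving* hits and compares genes by TF
name, not matrix accession — several matrices can represent one
factor, and presence/absence per factor is what the comparison is
about. Whether the original sharing analysis applied the chromatin
filters to every factor or only to the highlighted ones is not fully
explicit; this pipeline applies them uniformly.

# Quantification conventions

* **Comparative Ct:** amplification efficiency is fixed at 2 (classic
  `2^(−ΔΔCt)`), replicate Ct values are averaged *before* ΔCt, the
  reference gene is 18S rRNA, and the calibrator defaults to the
  earliest time point (6 h in the standard design) — the calibrator
  is named in every output header because the original figures do not
  name theirs.
* **Correlation:** Pearson across matched time points (≥ 3), with a
  configurable classification threshold r ≥ 0.7 standing in for the
  qualitative "correlates well". A zero-variance profile yields an
  explicit `"undefined"` rather than NA arithmetic.
* **Luciferase:** per reaction, mean of the three firefly reads over
  Renilla; per arm, mean over replicates; fold = treated/untreated.
  The fold is invariant to rescaling any replicate's luminescence.
* **Morphology:** a cell is tubular iff any particle is strictly
  longer than 2 µm after discarding particles below 0.3 µm; 2.0 µm
  exactly is spherical (the tubular class is defined by "> 2 µm").

# The synthetic world

The generator (`build_promoter_fixture()`) is first-class, tested
code, not a throwaway fixture. It emulates:

* 10-kb promoters (uniform base composition by default; a GC knob
  exists) with motif instances planted at **controlled relative
  scores**: `sample_site()` finds a k-mer inside a requested score
  band by randomised depth-first search with exact branch-and-bound
  pruning, so an exhausted search *proves* a band infeasible — e.g.
  the toy two-column motif's achievable spectrum is exactly
  {0, 0.5, 1}, so a [0.90, 0.95] band errors rather than loops.
* matched histone and TF-cluster BED tracks encoding each site's
  intended fate: active sites get an overlapping activating mark and
  a cluster at the requested score; silent sites additionally get an
  H3K27me3 overlap, or a sub-500 cluster.
* qPCR tables with programmed fold inductions
  (`Ct = base − log2(fold) + N(0, σ)`) against a flat 18S control,
  luciferase plates with programmed treatment responses and a
  near-zero promoterless control, and per-cell particle-length
  tables.

Background windows that happen to score above threshold are re-drawn
locally until a scan recovers exactly the planted truth; the motif
panel's consensi were chosen mutually dissimilar (worst cross-motif
consensus relative score ≈ 0.81, below the 0.89 threshold) so planted
sites of one factor cannot masquerade as another. Planted sites are
spaced so histone marks cannot leak across sites of differing status
(≥ 2×window + 100 bp in mixed genes).

The **motif panel is synthetic**: JASPAR-style accessions and real TF
names, but constructed peaked counts (85–95% consensus base per
column). Likewise the three-promoter fixture realises the published
*sharing structure* (β∩γ = {SMAD2/3, ATF4, SOX10, PPARγ}, α∩β = ∅,
α∩γ = {PPARα}) in constructed sequences. A green end-to-end test
therefore establishes that the *procedure* — scanning, thresholding,
filtering, set comparison — behaves exactly as specified on inputs
with known truth; it does not establish anything about the real PEX11
promoter sequences, real JASPAR matrices, or real HepG2 chromatin,
none of which are shipped. Real data will additionally contain
ambiguous bases, repeat-induced near-motifs, correlated histone
domains and multiple matrices per TF, which the generator does not
model.

The 1,302-bp construct fixture mirrors the cloned promoter fragment
design: one above-threshold 6-bp SMAD2/3 core in the wild type;
excising it yields the 1,296-bp mutant, and a rescan of the mutant
finds nothing — verified by scan, not by construction.

# Numerical choices and degenerate inputs

* Scores are compared to the threshold in double precision with no
  rounding; the scanner and the exhaustive enumeration oracle agree to
  1e-9 by test.
* `sample_site()` accepts a band with a 1e-9 relative tolerance at its
  edges so floating-point column sums cannot exclude an exactly
  attainable bound.
* Coordinates are 0-based half-open on the reference strand (BED
  convention) everywhere outside promoter-local offsets, which are
  0-based on the gene's strand; `map_to_genomic()`/`map_to_local()`
  are exact inverses by property test.
* Empty inputs are non-errors where a sensible empty output exists
  (empty motif list → empty hit table; empty surviving set → empty TF
  set) and errors where silence would mislead (missing reference gene,
  calibrator, untreated arm).

# Statistical note on the noisy-recovery check

The ΔΔCt recovery check runs 20 seeds of a programmed k-fold induction
with Ct noise σ = 0.1 and 4 replicates. The per-seed ΔΔCt standard
deviation is 0.1 by construction (≈ 7% multiplicative error at 1σ), so
demanding every seed land within 10% would fail ~17% of the time per
draw by design rather than by defect. The acceptance test therefore
checks the *mean* recovered fold across the 20 seeds against the 10%
band (standard error ≈ 2%), which tests the estimator's calibration
rather than the noise realisation.

# Known limitations

* No p-value calibration of PWM scores, higher-order background
  models, or motif discovery — scanning known motifs only.
* The chromatin filter consumes interval BED tracks; no signal-track
  (bigWig) quantification or peak calling.
* Start-codon anchoring ignores transcript models and alternative
  promoters by design.
* Whole-genome-scale scanning is out of scope: the scanner is linear
  in promoter length × motif count and comfortable at tens of
  promoters × tens of motifs, not thousands of each.
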