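---
title: "Methods: methylome segmentation, DMR calling and 4C domainograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome segmentation, DMR calling and 4C domainograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylodyn)
```

# Scope and data model

methylodyn analyses single-CpG methylomes of differentiating cell
populations (the motivating system is the mouse small-intestinal crypt to
villus axis, with a hair-bulge stem-cell methylome as an outgroup), plus
the associated expression, annotation and 4C-seq contact data. All
coordinates are 0-based and half-open, everywhere: a single convention
removes an entire class of off-by-one bugs. CpGs are indexed by the
position of the C on the plus strand with both strands collapsed into one
(methylated, total) count pair. The per-region summary used throughout is
*weighted methylation*, `sum(meth) / sum(total)` — count-weighted so that
low-coverage CpGs do not get an equal vote, and exactly additive under
splitting a region into subregions. A region with no covered CpG yields
`NA` ("no data"), never 0.

# Segmentation into hypo-methylated regions

## Model

A two-state hidden Markov model over the CpG sequence. Emissions are
beta-binomial, parameterised per state by mean `m` and precision `r`
(`alpha = m*r`, `beta = (1-m)*r`): two orthogonal, interpretable knobs,
with `r -> Inf` recovering the binomial. The beta-binomial absorbs the
overdispersion of bisulfite counts relative to binomial sampling
(biological heterogeneity between cells plus technical variation).
Transitions act between consecutive CpGs; the chain is *reset* at deserts
(inter-CpG gap > `desert_size`, default 1000 bp) because methylation
dependence does not plausibly persist across kilobase gaps with no data.

## Fitting

`fit_segmentation()` runs Baum–Welch EM. The E-step is a scaled
forward–backward pass (compiled, per desert block, restarted with the
initial-state distribution). The M-step updates transitions and initial
probabilities in closed form; the beta-binomial emission parameters have
no closed-form update, so each state's weighted log-likelihood is
maximised numerically (Nelder–Mead on logit-mean/log-precision), starting
from the current values and falling back to them if no improvement is
found. This is a generalised EM: the observed-data log-likelihood is
non-decreasing at every iteration, which the test suite asserts on the
whole trace. Convergence is declared when the relative log-likelihood
change falls below `tol` (default 1e-5); non-convergence within
`max_iter` returns the best parameters with a warning. After fitting,
states are relabelled so state 1 is the lower-mean (hypo) state —
otherwise the two-state model is only identifiable up to permutation.
Numerical guards: emission means are clamped to [1e-6, 1-1e-6] and
precisions to [1e-3, 1e6]; zero-coverage sites contribute a likelihood of
1 to both states (they carry no information but keep the chain intact);
a methylome whose sites are all uncovered is an error, as is one with
fewer than 50 covered CpGs (too little data to identify four emission
parameters plus transitions).

## Decoding

`call_hmrs()` uses posterior decoding: HMRs are maximal runs of CpGs with
posterior hypo probability strictly greater than 0.5, broken at deserts.
A posterior of exactly 0.5 is assigned to the hyper state — the
conservative tie-break, yielding fewer HMRs. Each HMR spans first to last
member CpG and carries CpG count, weighted level and mean posterior.
Posterior decoding (rather than Viterbi) matches the per-CpG posterior
semantics of the DMR step and is checked against an exhaustive
path-enumeration oracle on small instances.

# DMR calling

`call_dmrs(a, b, ...)` takes two methylomes on the same genome manifest
and their HMR sets. Candidates are the symmetric difference of the two
HMR interval sets — regions hypo-methylated in exactly one population.
Candidate fragments separated by at most `merge_gap` bp (default 1000,
the same scale as the desert size) are fused first: a single differential
region interrupted by a short stretch of ambiguous posterior support is
one candidate, not several. Each candidate is summarised by its weighted
methylation in both methylomes; `delta = level_a - level_b` with `a` the
pre-differentiation condition, so `direction == "loss"` (delta > 0) means
methylation lost upon differentiation. Emitted DMRs must have at least
`min_cpgs = 10` CpGs covered in both methylomes and `|delta| >= 0.40`;
both boundaries are inclusive (a candidate with exactly 10 CpGs and
exactly 40% difference passes; 9 CpGs or 39.9% does not), with a 1e-9
slack on the delta comparison so that exact decimal thresholds survive
floating-point arithmetic. The 40% difference is computed on weighted
region methylation, not the mean of per-CpG levels — robust to
low-coverage CpGs; per-CpG Fisher exact tests (methylated vs unmethylated
counts across conditions) are reported per candidate (`min_p`,
`frac_sig`) but deliberately not used as a filter, since the defining
filters are the CpG count and the difference. Calling with the
methylomes swapped returns identical intervals with directions flipped.

# TSS, expression and enrichment

`tss_methylation()` summarises the window `[tss - 1000, tss + 1000)`. The
coverage filter counts *CpG data-points*, interpreted as the total number
of read observations over window CpGs (summed coverage): 80 distinct CpGs
in a 2-kb window is near the biological ceiling of CpG density, so the
summed-coverage reading is the plausible one; counting distinct covered
CpGs is available via `datapoint_mode = "cpgs"`. A gene passes only if it
meets the threshold in *every* compared methylome; failing genes are
flagged, never dropped. `differential_tss()` uses a strict inequality
(difference > 0.50): "more than 50%" excludes exactly 50%.

`de_genes()` computes `log2FC = mean(B) - mean(A)` on log2-scale values
and an equal-variance two-sample Student t-test. "Two-fold on log2 scale"
is `|log2FC| >= 1` (boundary inclusive). When both groups have zero
variance, p is 1 for identical means and 0 otherwise. No multiple-testing
correction is applied by default, matching the per-gene P < 0.01 usage
this models; Benjamini–Hochberg is one flag away (`adjust = "BH"`).

`dmr_expression_enrichment()` draws `n_perm` uniform gene sets of the
same size as the DMR-associated set and reports
`p = (1 + #{perm >= observed}) / (n_perm + 1)` — the add-one correction
keeps p in `[1/(n_perm+1), 1]` and finite-sample valid. The null is
exactly hypergeometric, which the tests exploit as an oracle.

# Genomic elements

`build_elements()` derives TSS windows (±1 kb), exons, introns (gaps
between consecutive exons) and — when the gene table carries a CDS —
5'/3' UTRs as the transcript portions outside the CDS (at this element
granularity the UTR intervals are not intersected with exons). Repeats
pass through under their SINE/LINE/LTR classes. An address may carry
several classes; each interval carries exactly one label.
`element_change()` reports `100 * (level_b - level_a)` per element and an
*unweighted* per-class mean over elements with data in both conditions —
each element gets one vote ("average per element"), rather than letting
CpG-rich elements dominate; this choice is config-visible in the output,
which retains all per-element values.

`rank_sum_test()` is the shared two-sample core: exact (via the
Mann–Whitney U null distribution) when the pooled sample has at most 12
observations and no ties; otherwise a normal approximation with midranks,
tie correction and continuity correction. Enumeration with midranks would
be possible, but the corrected approximation is the standard choice and
is validated against both brute-force enumeration and a permutation
oracle. If all pooled values are identical, p = 1 by convention (no
evidence either way).

# 4C domainograms

Blind fragment ends (no secondary-cutter site between the flanking
primary sites) follow a systematically different count distribution than
regular ones. `normalize_classes()` maps both classes onto the rank-wise
mean of the two class quantile functions, interpolated at midrank
positions — for equal class sizes this coincides with classic two-column
quantile normalization (mean of order statistics); for unequal sizes the
interpolation generalises it, with the Kolmogorov–Smirnov distance
between the normalized classes bounded by `1/min(n_blind, n_regular)`.
Ties share midranks and therefore receive equal normalized values, which
also means exact distribution equality is attained only on tie-free
data — an accepted property of every tie-respecting normalization.

`window_test()` compares the window of `w` consecutive normalized counts
starting at `i` with its two full flanking windows (2w values pooled),
one-sided: the alternative is "window greater", because the statistic
exists to detect *enrichment* of 4C signal. Windows whose flanks are not
both fully inside the track are "untestable" (`NA`), a result, not an
error. `build_domainogram()` assembles the −log10 p matrix over window
sizes (default {2, 5, 10, 20, 50, 100} fragments — a dyadic-ish ladder
from the finest testable scale to domain scale) with p floored at 1e-16
for finite display. `call_interactions()` thresholds cells (default
p < 1e-3), expands each significant cell to the fragment span it covers,
and merges across adjacent indices and window scales by interval union,
keeping the best p and the supporting scales. `link_viewpoint()` drops
calls farther than 750 kb from the viewpoint and links each remaining
call that comes within 5 kb of a TSS to the nearest such gene, annotated
with that gene's expression change; calls within 5 kb of a TSS are
*kept and linked* (selected), not discarded — the reading under which
promoter-contacting loops are reported rather than thrown away. All
distances are edge-to-edge with overlap = 0.

# DMR context and TF binding

`annotate_dmrs()` labels a DMR `TSS` if within 2 kb of an annotated TSS
and `intergenic` if farther than 2 kb from every gene interval; exon and
intron labels come from overlap, and a DMR overlapping several categories
is counted in each. A DMR within 2 kb of a gene body that overlaps no
genic feature and no TSS window would be unlabelled under the literal
rules; it falls back to `intergenic` so that every DMR carries at least
one label while `TSS` and `intergenic` remain mutually exclusive.
`peaks_near_dmrs()` pairs DMRs and peaks within 1 kb, edge-to-edge.
`tf_metaprofile()` excludes peaks closer than 5 kb to any TSS (a peak at
exactly 5 kb is kept: "at least 5 kb away"), then pools read counts in
distance bins around the peak summits (default ±2 kb at 50 bp; the flank
and bin width are display choices, exposed as parameters). Pooling is
count-weighted across peaks by default (`pooling = "mean"` averages
per-peak levels instead); the profile is invariant to peak order and
strand.

# The synthetic-data generator

The generator is the package's substitute for deposited sequencing data
and defines the conditions under which the pipeline is validated:

- `simulate_methylome()` draws CpG positions uniformly (≈10 CpGs/kb),
  Poisson coverage (mean 10, "roughly 10-fold"), and beta-binomial counts
  around two state means (0.10 hypo / 0.85 hyper, precision 15 — an
  overdispersion in the range estimated for real WGBS data). Planted
  HMRs (default 60 regions of 20–40 CpGs on a 2-Mb chromosome) put the
  genome-wide weighted methylation near 78%, the stem-cell value the
  package's defaults emulate.
- `simulate_differentiation_pair()` plants 43 loss-DMRs (hyper level
  dropping by delta = 0.5 over 15 CpGs) and 7 gain-DMRs (hypo blocks
  rising by delta), mirroring the real-data direction asymmetry, and
  applies a uniform downward shift to all non-DMR sites *calibrated so
  the total genome-wide drop equals `global_loss`* (default 0.04,
  i.e. 78% → 74%) with the DMR contribution included; the shift is
  clamped at zero (with a warning) if the DMRs alone exceed the target.
  Planted DMR regions therefore differ by exactly delta in expectation.
- `simulate_read_patterns()` models co-methylation of the first three
  CpGs per read as a mixture: with probability `rho` the read is coherent
  (one Bernoulli at the mean of the three site levels), else the calls
  are independent. `rho = 1` yields only fully methylated or fully
  unmethylated reads and `rho = 0` exact independence; in between, the
  per-site marginals are mildly distorted when the three levels differ —
  acceptable for a pattern-class generator, and documented.
- `simulate_4c_track()` lays fragment ends at jittered ~500 bp spacing,
  draws geometric (heavy-tailed) background counts whose mean decays from
  the viewpoint as a power law (`(1 + d/1e5)^-0.85`; the proximity bias
  is visible in real 4C but not parameterised, so a smooth monotone decay
  is assumed), samples blind fragments at rate 0.35 with means shifted by
  a factor 0.4, and multiplies means inside planted peaks by the
  enrichment. Setting `decay_exponent = 0` gives an exchangeable
  background — the correct null for calibrating a rank-sum statistic,
  since with decay the window-vs-flanks comparison is slightly
  conservative near the viewpoint (convex decay makes flank means exceed
  the window mean).
- `simulate_expression()` and `simulate_annotations()` provide Normal
  replicate intensities with planted ±log2fc shifts, and non-overlapping
  slot-placed genes with exon/CDS structure, repeats, and TF peaks
  placeable at planted methylation dips under a minimum TSS distance.

Every generator is a pure function of its parameters and seed, and every
generator emits a truth table.

What the generator does **not** emulate: mouse-genome base composition
and CpG islands, mapping artefacts, copy-number or repeat-copy effects,
replicate methylomes (one methylome per condition, as in the motivating
study), trans-chromosomal 4C contacts, and microarray preprocessing.
Passing tests demonstrate that the statistics recover planted structure
under the stated noise model — not that the pipeline is robust to every
artefact of real sequencing data.

# Validation choices and problem sizes

The test suite validates each statistic against an independent oracle:
beta-binomial PMF against numerical integration; HMM posteriors against
exhaustive path enumeration (≤ 12 CpGs, tolerance 1e-9); the rank-sum
exact branch against brute-force assignment enumeration (1e-12) and the
approximate branch against `wilcox.test` and a permutation oracle;
quantile normalization against the sorted-mean construction and limma;
the permutation enrichment against the hypergeometric tail. End-to-end
checks run at deliberately modest sizes chosen to keep the full suite
fast while leaving enough statistical resolution: 5,000-CpG methylomes
for parameter recovery (emission means within ±0.05, HMR CpG-level
F1 ≥ 0.9), three 20,000-CpG stem/villus pairs for DMR recovery (pooled
recall ≥ 0.9 — near the ceiling imposed by the 10-CpG/40% filters at
delta 0.5 and 10× coverage, where sampling noise alone drops ~5–10% of
planted regions below threshold), 400-fragment 4C tracks with 100 seeds
for null calibration (false-positive rate within 3 binomial SEs of the
nominal level per window size, on disjoint block-spaced cells) and
planted-peak recovery (≥ 95/100), and 100 no-signal pipeline runs that
must stay silent (zero DMRs and zero differential TSSs in ≥ 95).

# Known limitations

- The two-state model compromises when a methylome contains three
  effective levels (background hypo ≈ 0.06, partial DMRs ≈ 0.35, hyper ≈
  0.81): partially methylated DMRs decode with trimmed edges, which is
  the main cause of missed planted DMRs at the filter boundary.
- Beta-binomial M-steps are local optimisations; EM can in principle hit
  local optima for adversarial initialisations. The default
  initialisation (means 0.1/0.8, precision 10) is far enough from the
  boundary to be robust in practice.
- `read_methcounts()` reconstructs integer counts as
  `round(level * coverage)`, lossy only if the source file itself rounded
  the level.
- The permutation enrichment test assumes exchangeability of genes under
  the null; gene-length or expression-level confounding in real data is
  not modelled.
- p-values in the domainogram are not corrected for multiple testing
  across cells; the calling threshold (default 1e-3) plays that role
  operationally, as in visual domainogram analysis.
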