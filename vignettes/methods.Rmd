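---
title: "Models and methods: comparative 3D chromatin architecture across rearranged genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Closely related plant genomes — the motivating system is the cotton tribe,
where *Gossypioides kirkii* (n = 12) diverged from *Gossypium* species
(n = 13) roughly 10 million years ago — differ by inversions,
translocations and chromosome fusions/fissions. Each rearrangement leaves a
**synteny break**: a junction between collinear blocks of orthologous
genes. This package implements, as a tested and reusable pipeline, the
comparative analyses that relate such breaks to the hierarchy of 3D
chromatin architecture measured by Hi-C:

* normalization of binned contact matrices (iterative correction, plus a
  Poisson-regression covariate normalization),
* A/B compartment calling from the leading eigenvector of the
  observed/expected correlation matrix, and cross-species compartment
  switch classification on syntenic genes,
* insulation-based TAD detection with the boundary / body / inter-TAD
  interval partition used in plant genomes, conserved-vs-rearranged TAD
  classification, size grouping and break proximity,
* collinear block chaining from homolog tables, synteny-break derivation
  and the minimal-gene threshold sweep,
* shuffle-null and Fisher exact co-localization tests between breaks and
  architectural features,
* orthologous expression divergence |e1 − e2| on log10 RPKM and its
  contrasts over break adjacency and TAD conservation classes, and
* origin-stratified in-cis decay curves on fused (mosaic) chromosomes.

Real cotton data cannot be re-processed at desk scale, so the package's
first-class citizen is a **synthetic multi-species generator** with exact
planted truth; every caller is validated by recovery, calibration and power
experiments against that truth. This document records the models, the
parameter choices and their rationale, and the known limitations.

# The synthetic study system

## Ancestral genome

`simulate_ancestor()` lays out chromosomes with alternating A/B compartment
blocks (6–14 bins of 50 kb each, i.e. 0.3–0.7 Mb) and places genes
sequentially with mean spacing 10 kb, shorter in A blocks than in B blocks
(ratio 2.5), so that A compartments are gene-dense — the property that
later orients compartment calls, as in real genomes where A compartments
occupy gene-rich chromosome arms. Gene length is fixed at 2 kb: expression
contrasts, not transcript-length effects, are under test. An ancestral TAD
tiling (domains 80–200 kb separated by 10–40 kb intervals, on a 5-kb grid)
is attached to the ancestor.

## Rearrangements and inherited truth

`apply_rearrangements()` applies inversion / translocation / fusion /
fission events in gene-index coordinates and re-lays the derived genome
preserving each gene's ancestral intergenic gap, so local gene density —
and with it compartment structure — travels with the DNA. Provenance is
tracked per gene; **origin segments** are maximal runs of ancestrally
adjacent, consistently oriented genes, and every junction between segments
is a planted breakpoint.

Truth annotations are *inherited*, not re-drawn:

* compartment truth is the ancestral A/B structure mapped through the
  origin segments; optionally, B bins near junctions flip to A
  (`switch_near_breaks`), emulating rearrangement-induced B-to-A switches;
* TAD truth is the ancestral tiling mapped through origin segments. A
  domain fully contained in one segment travels with it (so TAD structure
  is conserved across species, including wholesale-moved domains); a
  domain straddling a junction is **destroyed** — its span becomes
  inter-TAD interval and its genes are recorded as having lost their
  insulated context.

`snap_events_to_boundaries()` optionally moves event cut points (within
±10 genes) so that junctions fall in ancestral inter-TAD gaps within 10 kb
of a domain corner. The per-endpoint probability (default 0.7) sets the
planted degree of break/boundary co-localization. Comparative Hi-C studies
report this co-localization qualitatively (boundary enrichment at high
significance), not as a rate, so the default is an artifact choice, made
once so that the planted effect is unambiguous at the demo scale of a few
dozen breaks.

## Forward contact model

Expected cis counts follow

$$\mu_{ij} = \mathrm{depth}\cdot \max(|i-j|,1)^{-\alpha}\cdot P_{ij}\cdot
T_{ij}\cdot b_i b_j,$$

with plaid factor $P_{ij}$ = `plaid_contrast` (1.6) when both bins share a
compartment label, TAD factor $T_{ij}$ = `tad_enrichment` (2.0) when both
bins lie in one true domain, and biases $b_i$ built from synthetic
covariates (effective length, GC, mappability) times log-normal noise
(sd 0.25). Counts are Poisson and exactly symmetric. In
`ancestral_preserving` mode, cis pairs from different ancestral chromosomes
within one (fused or mosaic) chromosome are dampened by 0.3 — ancestral
in-cis preservation is reported in the field only directionally, so the
magnitude is an artifact choice.
`depth` (expected count at one-bin distance) defaults to 500;
together with the factors above this gives the callers clear but not
trivial signal (boundary F1 well above 0.9, insulation tracks flat on
decay-only nulls), which is the stated design goal of the defaults. The
trans background is uniform and thin (`trans_depth`).

The generator emulates distance decay, plaid, domain blocks, bin biases and
origin dampening. It does **not** emulate loops, nested/hierarchical
domains, copy-number variation, restriction-fragment granularity, or
mapping artifacts; passing recovery tests therefore certifies the
algorithms' correctness on the modelled effects, not performance on every
property of real libraries.

# Normalization

`ice_balance()` estimates multiplicative bin biases by iterative
correction. Because a cis-only matrix is block-diagonal, biases are
estimated per chromosome and then rescaled so unmasked row sums equalize
genome-wide; bins below the 2% marginal quantile are masked and propagate
as missing, never as zero. Convergence is the coefficient of variation of
unmasked row sums (tol 1e-5, max 200 iterations). Two numerical facts are
worth recording: balancing forces equal row sums even on finite
chromosomes whose end bins genuinely see fewer neighbours, which inflates
end-bin corrections; and the solution absorbs smooth sampling noise into
low-frequency bias modes. Both are properties of the method, not bugs; the
TAD caller and the decay analysis account for them (below).

`hicnorm_lite()` fits, per chromosome, a Poisson regression of cis counts
on the logs of pairwise covariate products (effective length, GC,
mappability) with distance-decile fixed effects absorbed, and divides by
the fitted mean. The original method fits per fixed distance; absorbing
distance deciles is a documented simplification. Constant covariates fall
back to identity with a warning. The pipeline applies ICE first and the
covariate model second; on simulated matrices the residual Spearman
correlation between normalized values and covariate products is below
0.05.

# Compartments

`call_compartments()` works at 50 kb: per chromosome, observed/expected
transform, Pearson correlation of O/E rows, leading eigenvector, sign
oriented so that its correlation with gene density is non-negative, labels
by sign. Only the first eigenvector is used; chromosomes whose orientation
correlation is weaker than |r| = 0.3 are flagged for review rather than
silently labelled. Genes are assigned to the bin containing their
midpoint. Switch states (stableA/stableB/AtoB/BtoA) come from the two
species' bin labels at each syntenic ortholog; break-adjacent enrichment
uses a two-tailed Fisher test on {±10 kb of a break vs background} ×
{state vs other}, with Benjamini–Hochberg values reported alongside raw
ones.

On a fused chromosome simulated with strong origin dampening the leading
eigenvector tracks ancestral origin rather than the plaid; the demo
therefore simulates compartment-scale (50-kb) maps without origin
dampening, treating ancestral in-cis preservation as the fine-scale
phenomenon it is measured as (5-kb decay curves).

# TAD detection

`call_tads()` implements an insulation-score caller for the
non-side-by-side domain organisation of plant genomes, in four steps:

1. **Valley detection.** An insulation statistic (mean contact in the
   window×window square bridging each bin, window 50 kb) is computed on a
   bias-corrected O/E map, and local minima with a two-sided prominence of
   at least `min_depth` (0.1, in log2 units) mark inter-domain valleys —
   the "bottom points" of the domain interaction triangles. Prominence is
   evaluated by walking outward until the score rises by `min_depth` or a
   lower point appears, so wide valleys (large inter-TAD holes) remain
   detectable. A chromosome with no such minima yields no TADs.
2. **Membership.** The bias-corrected O/E map divides each bin pair by the
   two bins' long-range O/E levels (pairs more than 20 bins apart), which
   estimates residual bin biases without absorbing domain-scale structure,
   and then divides out long-range block factors estimated from the sign
   of the leading eigenvector of the far-O/E correlation (up to three
   passes: compartment plaid, and on mosaic chromosomes the ancestral
   origin factor). A bin is domain-like when its mean O/E with its 4
   nearest neighbours on at least one side exceeds the geometric midpoint
   of the 10th/90th percentile levels. Single-bin holes are filled, runs
   of up to 3 bins dropped, and runs are split at interior insulation
   minima (side-by-side remnants at rearrangement junctions).
3. **Corner refinement.** Each candidate's edges move (±3 bins) to the
   position maximizing inside-minus-crossing mean O/E over an 8-bin
   corner window.
4. **Acceptance.** A candidate becomes a TAD only if it spans at least
   `min_size` (25 kb), its mean intra-domain O/E exceeds
   `intra_flank_ratio` (1.2) times the mean O/E of edge-crossing pairs,
   and each edge faces a detected insulation valley (or the unscored
   chromosome end). Rejected spans become inter-TAD intervals.

Boundary regions are the domain corner ±10 kb; `tad_partition()` produces
the disjoint boundary/body/interval classes used by the co-localization
analyses. Insulation scores within two windows of a chromosome end are
dropped: balancing distorts end bins (truncated decay), and scores touching
that zone are unreliable.

Cross-species conservation follows the majority rule: a domain with more
than 4 syntenic genes is conserved when more than 50% of them fall in a
single best-covered domain of the other species (ties broken toward larger
reciprocal overlap, then leftmost; an "any-domain" mode is available
behind a flag). Size classes split at a per-species threshold (demo
65 kb); break proximity is judged on the domain plus its boundary regions.

# Synteny

`filter_homologs()` retains hits with e-value ≤ 1e-5 ranking in the top 5
matches of both partners. `chain_collinear()` chains anchors per
chromosome pair by dynamic programming into maximal monotone chains
(strictly increasing in species 1, strictly monotone either way in species
2). Between consecutive anchors a chain may skip at most `max_gap` = 30
genes without retained homologs and at most `skip_syntenic` = 5
homolog-bearing genes — the second bound is what prevents a chain from
bridging a rearranged segment that belongs in its own block. Consecutive
anchors on one target gene are collapsed (tandem convention). Chains are
extracted best-first, each anchor joining one block; blocks need
`min_genes` = 10 anchors and a Monte-Carlo permutation p below 0.05
(longest monotone subsequence of randomly scattered anchors in the block's
rank window; 1000 seeded permutations by default — a seeded
permutation estimate stands in for ColinearScan's closed-form block
significance, at the same acceptance threshold).

`derive_breaks()` walks retained blocks along each species-1 chromosome
and emits a break wherever the species-2 side is discontiguous: different
chromosome (fusion/fission when both flanks are terminal on their
species-2 chromosomes, else translocation), flipped orientation
(inversion), displacement beyond the gap rule, or a species-2 gap occupied
by another retained block (an inserted segment). Break intervals are the
half-open gap between block-end genes (1-bp points when empty); category
assignment is heuristic and labelled as such. Because a fusion junction is
invisible from the unfused side, the pipeline chains both directions.
`threshold_sweep()` re-derives breaks over minimal-gene thresholds
{5, 8, 10, 20, 30} and reports the knee (maximum second difference),
without auto-applying it; 10 is the working default.

# Co-localization statistics

`shuffle_intervals()` re-places intervals uniformly among non-overlapping
arrangements with the per-chromosome length multiset preserved, using the
exact spacing construction (draw n starts uniformly in the chromosome
length minus the total interval length, sort, offset by cumulative
lengths in random order). This is uniform by construction and cannot fail
to pack, which is why it replaces bounded rejection sampling; the
infeasible case (intervals longer than the chromosome) still errors.
`empirical_enrichment()` compares the observed overlap fraction of A in B
with its null under shuffling A, B or both (modes equal in distribution
under independence), with the +1-corrected empirical p. The
bedtools-style Fisher table treats ⌊genome length / mean interval length⌋
as the number of placeable slots; that n22 cell is a modeling convention,
so the permutation test is the recommended primary statistic, and both are
reported everywhere.

# Expression divergence

RPKM uses the table's total counts as library size; e is log10 of the
replicate-mean RPKM plus a pseudocount of 0.01 (zero handling and replicate
averaging order are not standardized; replicate-mean RPKM then log was
adopted and is flagged here).
Divergence is |e1 − e2| per ortholog pair. Group contrasts are Wilcoxon
rank-sum tests, exact for combined n ≤ 20 without ties.

In the demo, the planted divergence effect (factor 2.0) applies to
orthologs within ±10 kb of a break that are *not* inside a surviving
domain, and to all orthologs of destroyed domains — i.e. domain
stabilization dominates mere break proximity, which is exactly the
directional pattern under test: near-break > distal, rearranged-TAD >
conserved-TAD, and proximal ≈ distal within conserved TADs.

# Origin-stratified decay

`cis_decay_by_origin()` assigns every cis pair of a mosaic chromosome to
the same- or different-ancestral-origin stratum, reports mean normalized
contact per log2-spaced distance stratum, and tests the strata with a
**rank-sum test stratified by exact bin distance** (van Elteren
combination, tie-corrected). Stratification is essential: within a coarse
log2 stratum the two origin groups have different exact-distance mixtures,
and Poisson counts at different distances are not exchangeable even after
rescaling — a naive pooled rank-sum is wildly anti-conservative on null
data. The null-calibration experiment runs on bias-free raw decay-only
matrices: that isolates the statistic's calibration. With multiplicative
bin biases, thousands of pairs share a few hundred bins and *no* pair-level
rank test is calibrated (bin-level pseudo-replication); this limitation is
shared with the field's standard practice and is why the direction of the
effect, not the pair-level p alone, is the headline output.

# The demo system and the scorecard

`default_config()` builds a five-chromosome, 240-genes-per-chromosome
ancestor (~15 Mb) and three descendants with 6 events each (inversions,
translocations, one fusion in spC), sized so each comparison yields ~25
synteny breaks. Event intervals are laid out so that no derived-species
event overlaps a reference-species event on the same chromosome — every
junction is then flanked by chainable blocks in both scored comparisons.
Problem sizes throughout (50–500 simulations per calibration experiment,
200-bin balancing matrices, 20 simulated genome pairs) were chosen as the
smallest sizes at which the binomial/KS tolerances of the acceptance
checks are meaningful on one CPU.

`validate_report()` scores a run against its planted truth: compartment
agreement ≥ 0.95 per species; boundary recovery F1 pooled over all
simulated chromosomes ≥ 0.9 (per-species values are informational —
single-species F1 at a few dozen domains has sampling noise of several
points); break recall ≥ 0.9 and precision ≥ 0.95 (the dense, deliberately
interacting demo rearrangements are a harder condition than the clean
20-pair recovery experiment, which demands full recall); co-localization
significant under all three shuffle modes and the Fisher test;
B-to-A enrichment directionally right and significant per comparison with
the planted-effect detection judged on Fisher-combined evidence across the
two comparisons (the genome-scale power claim, p < 0.001 in ≥95% of
simulations, is certified by the dedicated switch experiment at realistic
break counts); the three expression contrasts; and same-origin dominance
in every populated decay stratum.

# Known limitations

* The forward model's magnitudes (plaid 1.6, TAD 2.0, dampening 0.3,
  depth 500) are artifact choices; the emulated phenomena are reported in
  the field qualitatively, not as effect sizes.
* The TAD caller targets block-enriched, gap-separated domains; nested or
  loop-anchored structures are out of scope, as are directionality-index
  or HMM callers.
* Rearrangement junction categories are heuristic labels.
* Pair-level rank tests on contact values inherit bin-level
  pseudo-replication (discussed above).
* The conservation majority rule classifies a wholesale-relocated domain
  as conserved; that is intended (synteny within the domain is intact)
  but worth remembering when reading counts.
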