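---
title: "Comparative frog genomics with frogsynt: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative frog genomics with frogsynt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frogsynt)
```

# Scope

`frogsynt` re-implements, as tested and reusable functions, the statistical
machinery of a comparative chromosome-scale analysis of frog genomes:

* inference of conserved ancestral syntenic elements from one-to-one
  ortholog placements across species;
* classification of chromosomal rearrangements against centromere/telomere
  geometry and Poisson tests of karyotype-change rates on a dated tree;
* Hi-C nuclear-architecture statistics: matrix balancing, contact-based
  centromere inference, A/B compartment calling, the Rabl SSD and CTP
  statistics with a rotation permutation null, and inter-arm/territory
  enrichment tests;
* recombination landscapes from genetic maps (not-a-knot spline Marey
  smoothing), variant-site filtering, residual heterozygosity and the
  full-sib inbreeding expectation;
* tandem-repeat monomer clustering, regional enrichment, Jukes-Cantor
  repeat ageing and binned density/PCA landscapes.

Every analysis can be exercised on synthetic data with planted ground
truth; the generators are first-class, tested code. Assemblies, gene
annotation, read mapping, variant calling, linkage-map construction and
Hi-C read processing are upstream of this package: inputs are ortholog
tables, binned contact matrices, genetic maps, site tables and repeat
annotations. The package is organised as an analysis workflow: the numbered
scripts under `analysis/` are thin narrative drivers over the functions
documented here, and they are also the command-line surface — each one is a
plain `Rscript` that reads and writes TSV/JSON.

# Synthetic data as study conditions

The generators define the conditions under which recovery is demonstrated;
they emulate the statistical structure of the real data, not its raw form.

**Karyotype histories.** The default ancestral karyotype
(`ancestral_frog_layout()`) has 13 elements of 240-60 Mb, eight acrocentric
(centromere 1.5 Mb from an end) and five (sub)metacentric (centromere at
40%). The default tree (`default_species_tree()`) is ultrametric with seven
species, 1050 My of combined branch length and a trifurcating root with
short (10-12 My) basal stems — frog families radiated rapidly, so most
branch length is terminal. Default per-type rates
(`default_event_rates()`) place 8 Robertsonian fusions, 2 Robertsonian
fissions, 2 end-to-end fusions and 2 reciprocal translocations per 1050 My,
the scale of the inventory inferred for real frogs, plus inversions (which
do not count as translocations). Robertsonian breakpoints sit exactly at
centromere coordinates and end-to-end junctions exactly at coordinates
0/length, so replay is exact and event classification on simulator output
is unambiguous. Events whose geometric eligibility cannot be met on the
current karyotype (e.g. a Robertsonian fusion with fewer than two
centromere-terminal chromosomes) are skipped rather than recorded; at these
rates skips are negligible.

What passing tests show — and do not show: with eight acrocentrics the
Robertsonian-fusion partner pool has 28 unordered pairs, so independent
fusions of the *same* pair in different clades (which genuinely confound
any synteny-based root reconstruction) are rare but not absent; recovery of
the planted 13 elements runs at ~97%. Real data add noise sources the
generator does not model (assembly errors, missed orthologs, segmental
duplication), so the measured recovery rate is an upper bound on what the
procedure achieves in practice.

**Hi-C matrices.** Expected intra-chromosomal contacts decay as
`d^-alpha` (default `alpha = 1`), multiplied by a compartment factor
(`1 + w_ab` for same-label pairs; default `w_ab = 1.2`, a stark
checkerboard comparable to real Pearson maps) and augmented by a Rabl
"wing" between opposite arms at matched centromere distance (Gaussian of
width `sigma = 4` Mb, weight `w_r = 1.5`). Compartment blocks alternate
with truncated-exponential lengths (scale 6 Mb, cap 3x scale: a single
block must not swallow a whole arm, or there is no checkerboard to
recover). Inter-chromosomal contacts are a background `b` times a
territory factor, with Gaussian enrichments for centromere clustering,
telomere clustering, and matched *absolute* nuclear height (distance from
the centromere in bp, width `sigma_pol = 8` Mb). The absolute-height form
matters: because p arms are systematically shorter than q arms, matched
large heights exist mostly on q arms, which reproduces the mild concordant
(p-p + q-q) inter-arm excess observed in Rabl nuclei — a relative-arm-
coordinate polar term is arm-agnostic and cannot produce it. Counts are
Poisson-sampled at a requested total depth and the exact expectation matrix
is returned for oracle tests.

**Marey maps, pedigrees, variants, repeats.** Recombination-rate
landscapes are piecewise on a 500-kb lattice with a subtelomeric
multiplier (default 12x) and small lognormal noise, integrated into exact
monotone marker maps. Pedigrees implement strict full-sib mating with four
founder haplotypes and Poisson crossovers on the cM map (no interference —
the simplest model consistent with cM bookkeeping). Variant tables plant
exact pass/fail labels; depth outliers are placed far above the mode
because with ~10% outliers the depth SD is inflated by the outliers
themselves, so the lower `mode - 1.78 SD` bound falls below zero and only
the high side can separate the planted classes exactly. Tandem arrays are
>= 5 copies of > 10 bp monomers with point mutations at a set divergence
and a randomly rotated reported consensus, emulating the arbitrary phase of
tandem-repeat-finder output.

# Ancestral elements

`infer_elements()` formalizes what was expert curation in the original
analyses. Stage 1 groups genes by their exact cross-species chromosome
signature. Stage 2 asks, for every pair of signature clusters, whether the
root state of the binary together/apart character (same chromosome or not,
per species) is "together", reconstructed by two-state minimum-change
(Sankoff) parsimony — the exact equivalent of Fitch parsimony on binary
trees that also handles the trifurcating (unrooted) root correctly. Pairs
unambiguously "together" at the root are merged; ties resolve to "apart"
so that merging stays conservative (the tie-to-together alternative was
measured and over-merges badly). Connected components of the merge graph
are the elements, labelled `A`, `B`, ... in the chromosome order of a
configurable reference species.

Two-state maximum-likelihood root reconstruction (Felsenstein pruning with
a symmetric rate) was evaluated and rejected: at realistic rates the long
terminal branches saturate and recovery degrades to 85-92%, versus 96-98%
for parsimony.

`conservation_fraction()` needs an operational rule the source analyses
never state: here a gene is *conserved* when, in every species, it lies on
a chromosome hosting at least `min_support = 3` genes of its own element in
that species — i.e. the gene travels with its element everywhere, and
isolated placements break conservation. `element_proportions()` attributes
chromosome bp to elements in proportion to element gene counts when a
chromosome hosts several elements (post-fusion).

# Karyotype rates

`classify_junction()` calls a junction Robertsonian when all breakpoints
fall within `eps_c` of a centromere, end-to-end when all junctions fall
within `eps_t` of chromosome ends, and reciprocal otherwise; the defaults
(5 Mb each) are the pericentromere scale of large frog chromosomes and are
configurable, as are the terminal windows of the random-break model.
Robertsonian is checked first, so an acrocentric fusion — near a centromere
*and* near an end — classifies as Robertsonian.

`count_translocations()` counts a four-way reciprocal event as three
pairwise rearrangements by default (a composite of three pairwise
exchanges). Note the published category sum (8 + 2 + 1 + 3 = 14) differs
from the printed total of 17 translocations; the headline
one-change-per-62-My rate uses the printed 17 over 1050 My, and both counts
are surfaced.

`branch_poisson_test()` reports both the smaller one-sided tail and the
tail-doubled two-sided p (capped at 1). Both conventions are surfaced
because the published branch tests mix them: ~200 My of stasis at one
change per 62 My gives a one-sided `exp(-200/62) = 0.040`, while six events
at expectation ~1 gives a doubled `1.2e-3`, printed as `1e-3`. Family-wise
correction across branches uses Hochberg step-up.

# Hi-C architecture

**Balancing.** `balance_matrix()` implements Knight-Ruiz balancing as the
inexact-Newton/conjugate-gradient iteration, pre-scaled by the mean row sum
for conditioning, plus ICE (alternating row scaling) as a slower reference;
both target unit row sums on the non-masked submatrix and they agree to
1e-4 on positive matrices. Zero-coverage bins are masked (`NA` weights).
Non-convergence is an error carrying the residual, never a silent result.

**Centromeres.** The wing score of candidate bin `c` averages
distance-normalized (O/E) contacts `M[c-d, c+d]` over `d = 1..D` with `D`
the shorter candidate arm; scores are shrunk toward the O/E background of 1
with three pseudo-pairs so single noisy anti-diagonal pairs near chromosome
ends cannot win. The intra-chromosomal argmax is refined by agreement with
the inter-chromosomal centromere-cluster signal (mean balanced contact to
the other chromosomes' current calls, iterated twice). Calls are flagged
low-confidence when the peak is below 1.5x the median candidate score, and
edge/acrocentric when within 3 bins of an end. A centromere whose short arm
spans fewer than ~5 bins is not localizable at bin resolution; such cases
are reported as flagged edge calls rather than precise positions.

**Compartments.** Per chromosome, the O/E matrix's Pearson correlation
matrix is decomposed and the compartment loading is the eigenvector that
best correlates with gene density among the leading three. On strongly
Rabl-organized chromosomes the *first* eigenvector can capture the p/q arm
split rather than the checkerboard; selecting by gene-density correlation
(as several published pipelines do) makes the call robust while preserving
the usual behaviour — on most chromosomes the selected eigenvector *is*
PC1. Signs are oriented so A (positive) is gene-rich. Segment statistics
report arithmetic and geometric mean lengths of maximal same-label runs.

**Rabl statistics.** Bin contact profiles are distance-normalized (O/E)
before the PCA that embeds bins in PC1-PC2: removing the decay keeps the
embedding from collapsing onto chromosome position while retaining the wing
and the inter-chromosomal polarity. Scores are standardized per component.
`rabl_ssd()` pairs the i-th p-arm and q-arm bins counting away from the
centromere and averages squared distances over pairs, then over chromosomes
with both arms >= 5 bins (excluded chromosomes are reported). Published SSD
magnitudes are treated as qualitative ordering targets only, since the
original normalization is not fully specified; what the package guarantees
(and tests) is the ordering — SSD decreases monotonically with planted wing
strength and is ~0 for exactly mirror-symmetric arm profiles.
`rabl_ctp()` gives each bin a polar coordinate `u` (0 at the centromere, 1
at the telomere, within its arm) and reports the ratio of mean balanced
inter-chromosomal contact among pairs with `|u_i - u_j| <= 0.2` to the rest.

**Permutation null.** `permutation_test()` rotates bin order circularly
and independently within each chromosome: distance decay and marginals are
preserved, arm alignment is destroyed. `p = (1 + #{null >= obs}) / (n + 1)`,
one-sided. Small rotations resemble the identity, which is the honest price
of this null; with the default simulations both SSD and CTP reject at
p < 0.01 with 499+ rotations.

**Enrichment tests.** `interarm_enrichment()` classifies inter-chromosomal
contacts into concordant (p-p + q-q) vs discordant (p-q) and compares
against the contingency expectation from arm marginal contact sums
(chi-square, df = 1); a bin-count expectation is available as an option.
`territory_enrichment()` builds the K x K inter-chromosomal count table.
Its diagonal is structurally zero, so expectations come from iterative
proportional fitting of the marginal products on off-diagonal cells — a raw
marginal product is visibly biased at small K. The global chi-square is
reported with `(K - 1)^2` degrees of freedom (81 for ten chromosomes),
matching the published convention, with Hochberg-corrected standardized
residual tests per pair.

# Recombination and variation

`smooth_marey()` fits the not-a-knot cubic spline (third-derivative
continuity at the second and penultimate knots) to cM vs bp and takes the
analytic derivative on a 500-kb lattice. The solver is written here because
base R's `splinefun` has no not-a-knot mode; it is oracle-checked by exact
reproduction of cubic polynomials. Negative derivatives (spline overshoot)
are clamped to zero and counted, never silently. Region classes follow the
extended-subtelomere geometry: terminal 30 Mb of (sub)metacentrics, with a
15-Mb pericentromeric exclusion carved out on acrocentrics, and a separate
5-Mb pericentromere class; medians are compared with two-sided two-sample
Kolmogorov-Smirnov tests under Hochberg correction.

`filter_variant_sites()` applies, in order: biallelic; depth within
`mode ± 1.78 SD` (modal integer depth; SD over retained biallelic sites);
allele balance in [0.3, 0.7] for heterozygous genotypes; and optionally
parental informativeness (parents fixed and different, depth >= 10).
`heterozygosity_windows()` counts heterozygous SNVs per kb in 500-kb
windows sliding every 50 kb and calls blocks as runs of >= 3 windows above
a threshold (default 10% of the mean non-empty window density — the
original block-calling rule is unpublished, so both knobs are explicit
configuration). Block bounds are trimmed by `window - step` per side to
deconvolve the window width, then converted to cM by linear interpolation
on the genetic map; the heterozygous map fraction is block cM over total
cM. With blocks covering 125.12 cM of a 1070.16 cM map this reproduces the
11.7% residual-heterozygosity figure.

`simulate_inbred_pedigree()` defines generation `g` individuals as the
offspring of the generation `g - 1` pair (generation 1 are the founders'
children), so per-locus non-IBD probability follows the classical
recurrence `H_t = H_{t-1}/2 + H_{t-2}/4` with `H_0 = H_1 = 1`, whose exact
solution is `1.1708 x 0.80902^t - 0.1708 x (-0.30902)^t` — the cited
`1.17 x 0.809^t` for practical `t`. The map-averaged simulated fraction is
unbiased against this expectation (checked at 3 SE for t in 10..20).

# Repeats

`build_monomer_db()` makes clustering rotation-invariant by aligning each
candidate against the head-to-tail dimer of a cluster seed (both strands),
joining at >= 75% identity over >= 45% of the monomer length — the
thresholds of the published clustering — with greedy centroid assignment in
length-then-lexicographic order for determinism. The published BLAST-based
footprint mapping is replaced by direct interval footprints of the
simulated arrays; E-value semantics are not reproduced.
`region_enrichment()` ranks clusters by ROI density over rest-of-genome
density with a 1-bp pseudocount on the rest footprint (the original
"normalized ratio" is not fully specified; this is the documented choice —
note the pseudocount intentionally breaks exact scale invariance for
clusters absent outside the ROI). `jc_distance()` is
`-(3/4) ln(1 - 4p/3)`, erroring at `p >= 0.75`. `tetramer_enrichment()`
counts motifs on both strands by default and flags motifs absent from the
tandem set. `binned_density()` supports the three published window/step
settings (1 Mb/200 kb repeats, 1 Mb/50 kb GC, 250 kb/12.5 kb genes);
`density_pca()` standardizes columns, smooths component scores with a
cubic smoothing spline and correlates them against a compartment track.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open bp throughout; genetic maps are in cM.
* All randomness flows through explicit `seed` arguments; replicate
  streams are derived deterministically (`seed + replicate`).
* KR tolerance 1e-8 on the row-sum residual, 1000 outer iterations;
  degenerate (all-zero) matrices and non-convergence are errors.
* Constant correlation matrices make the compartment eigenvector
  degenerate: error, not a silent call.
* `karyotype_change_rate()` with zero events returns an `NA` sentinel with
  a note, never divides by zero.
* Ties in element labelling break lexicographically; monomer clustering
  order is fixed by length then name.
* Marey grids cover the marker span only; extrapolated rates are `NA`.

# Problem sizes

The test suite and drivers are sized for a single CPU: Hi-C simulations of
5-10 chromosomes at 1-Mb bins (230-1200 bins), histories of 400-2000
genes, 100-replicate recovery experiments, pedigrees of 300-500 replicates,
and permutation tests of 499-999 rotations. These sizes were chosen so the
statistics operate in the same regime as the real analyses (hundreds of
bins per chromosome, thousands of orthologs) while each driver finishes in
minutes.

# Known limitations

* Element inference is synteny-only: independent Robertsonian fusions of
  the same chromosome pair in different clades are genuinely confounded
  and resolve as a single ancestral element, as they would for any method
  without junction-sequence evidence.
* The Hi-C generator has no translocation/structural-variant artifacts, no
  mapping noise, and territory factors are chromosome-level; inference
  results on it bound, not guarantee, real-data behaviour.
* Sex-averaged maps only; sex-specific recombination is out of scope.
* The pedigree model assumes no interference and no selection; the
  published excess heterozygosity attributed to non-full-sib matings is
  therefore *expected* to deviate from this model's predictions.
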