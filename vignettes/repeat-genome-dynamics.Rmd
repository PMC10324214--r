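---
title: "Repeat landscapes, microsatellites and genome-size evolution: methods"
author: "repeatscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat landscapes, microsatellites and genome-size evolution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`repeatscape` implements the comparative-genomics toolkit used to dissect how
repetitive DNA shapes genome-size variation across a species panel: repeat
annotation statistics and divergence landscapes, transposable-element (TE)
diversity indices, microsatellite (SSR) scanning, LTR retrotransposon
insertion dating, genome partitioning, Brownian-motion ancestral-state
reconstruction, and an ordinary least-squares correlation battery. This
vignette records the models, the tunable parameters, and the design choices
behind each stage, and what the synthetic-data generator does and does not
emulate.

## Repeat totals and divergence landscapes

A RepeatMasker annotation assigns each genomic copy of a repeat a
`class/family` string and a percent divergence from the library consensus.
`classify_te()` reduces the raw string to one of ten subclasses (LINE, SINE,
LTR, DNA, rolling-circle, satellite, simple repeat, low complexity, unknown,
other) by matching the token before the first `/`, after stripping
RepeatMasker's trailing `?` uncertainty marker. The mapping is total: anything
unrecognized is `OTHER`, never an error, so a new library never breaks a run.

`compute_landscape()` bins each record's aligned span into the half-open
divergence bin `[i, i + bin_width)` of its subclass and expresses coverage as
percent of the genome. Defaults are 1% bins over 0–50%, the conventional
landscape resolution; records at or beyond the axis end are dropped and
counted rather than clamped, so bin totals plus the dropped fraction always
reconcile exactly with `compute_te_totals()`. The divergence column of the
`.out` file is used directly as the age axis; re-aligning copies to apply a
CpG-adjusted Kimura correction from `.align` files is out of scope. Overlap
resolution is off by default (matching raw RepeatMasker tallies); a `merge`
mode flattens same-subclass overlaps when coverage semantics are wanted.

Landscape shape is a proxy for TE age structure: a single recent peak means a
young burst, multiple peaks mean successive expansions with poor deletion of
old copies. `classify_landscape_shape()` smooths total coverage per bin with
a centered moving average (default width 3 bins) and calls peaks at local
maxima of at least a fraction (default 0.2) of the global maximum. One peak
at divergence ≤ 5% is `L_SHAPED`; one older peak `UNIMODAL_OLD`; exactly two
peaks `BIMODAL`; more `MULTI_PEAKED`. The 5% boundary is the standard
"recent burst" criterion; the smoothing window and prominence fraction are
exposed because shape calling on published landscapes is typically done by
eye, and these two knobs are what a reader implicitly applies.

## TE diversity indices

TE subclasses are treated as the "species" of an ecological community whose
individuals are occupied base pairs. With `n_i` the bp occupied by subclass
`i` and `N = Σ n_i`:

* Simpson: `D = 1 − Σ n_i (n_i − 1) / (N (N − 1))` — the probability that two
  TE base pairs drawn without replacement belong to different subclasses.
* Shannon: `H = −Σ p_i ln p_i` with `p_i = n_i / N`.

The `n(n−1)` form requires count semantics, so occupied bp counts (not genome
proportions) are the inputs; this is the only self-consistent reading of the
index pair. By default the indices are computed over the four interspersed
subclasses (LINE, SINE, LTR, DNA); rolling-circle elements are reported in
totals but excluded from the four-subclass diversity input, and a
`level = "family"` mode recomputes both indices over raw class/family strings
for sensitivity analysis.

## Microsatellite scanning

`find_perfect_ssrs()` reports maximal, non-extendable tandem runs of
primitive motifs of 1–6 bp. Minimum repeat counts default to 12, 7, 5, 4, 4,
4 for mono- through hexanucleotides — the usual genome-survey thresholds —
and are fully configurable. A run is reported under its shortest period
(`(ATAT)×4` is `AT × 8`), runs touching N are excluded, and reported loci are
non-overlapping, chosen leftmost-first with shorter motifs winning ties.
Repeat numbers may be fractional because a maximal run can end mid-motif.

`find_imperfect_ssrs()` uses greedy seed-and-extend: perfect runs of at least
3 repeats and 8 bp seed an extension that walks outward tracking the motif
phase, scoring match +1, mismatch −1, gap −2. At a mismatching base a
one-step lookahead chooses between substitution, insertion and deletion,
preferring whichever realigns the next base (substitution first, so the
walk is deterministic). Extension stops at N, when the running score hits
zero, or after more than 2 consecutive edits, and each side is trimmed back
to its best-scoring point; loci scoring below 12 are discarded, and loci that
turn out to be perfect and above the P-SSR thresholds are left to the perfect
scanner. Compound SSRs (adjacent tracts of different motifs) are deliberately
not merged or reported. The scoring constants fix the algorithm precisely so
results are reproducible; all are exposed.

Motifs are standardized to the lexicographically smallest string among all
cyclic rotations of the motif and of its reverse complement, grouping the
motifs that describe the same tandem array read from either strand at any
phase. Summary statistics use the *valid* (non-N) genome length: relative
abundance is loci per Mb and relative density bp per Mb of valid length. A
raw "per bp" ratio would put all values at the 10⁻⁵ scale; per-Mb is the
field convention and monotone-equivalent.

## LTR insertion dating

The two LTRs of a retrotransposon are identical on insertion; their
divergence dates it. The module consumes 5′/3′ LTR pairs (or a precomputed
divergence table) — structural discovery of intact elements is out of scope
because the dating computation, not the structural scan, is the analysis.
Pairs are globally aligned (Needleman–Wunsch, match +1, mismatch −1, gap −2,
deterministic traceback preferring diagonal, then up, then left, implemented
in C++), `p` is the mismatch fraction over columns with two non-gap, non-N
residues (indel and ambiguous columns are excluded from numerator and
denominator), the Jukes–Cantor correction `k = −(3/4) ln(1 − 4p/3)` undoes
multiple hits (defined for `p < 0.75`; beyond that divergence is saturated
and an error is raised), and the age is `T = k / (2r)` with the neutral rate
defaulting to `r = 1.38 × 10⁻⁸` substitutions/site/year, the amphibian
neutral rate used for anuran dating. Age histograms bin at 0.5 My by default,
with < 1 My as the conventional "recent insertion" boundary.

## Genome partition

`partition_genome()` divides each genome into exonic, intronic and intergenic
territory from GFF3: genic = union of `gene` spans, exonic = union of exons
clipped to genic, intronic = genic − exonic, intergenic = the rest. The three
territories always sum to the genome length exactly — this invariant is
property-tested on random annotations. Introns are enumerated per gene from
the union of that gene's exons across isoforms, so alternative transcripts
never double-count intronic bp; overlapping genes share territory but keep
their own intron enumerations. Counts and mean lengths come from this
enumeration. Runs of N of at least `gap_min_run` (default 10 bp; the
threshold below which an N run is treated as ambiguity rather than an
assembly gap) intersected with intronic/intergenic territory give the two gap
tallies. Means over zero elements are reported as 0 with count 0 rather than
NA so downstream tables stay numeric.

## Ancestral states under Brownian motion

For a continuous trait (genome size in Gb, TE proportion in %) evolving by
Brownian motion on a rooted tree with branch lengths, the maximum-likelihood
estimate of each internal node's state is the generalized-least-squares root
estimate of the tree re-rooted at that node — the recursive
inverse-branch-length-weighted mean of the tips. `anc_states_ml()` computes
all node estimates in two message-passing sweeps (an upward pass of
subtree means and variances, a downward pass of rest-of-tree messages), which
is linear in tree size and handles polytomies natively, with no random
resolution. The ML Brownian rate `σ²` is the GLS sum of squares divided by
the number of tips, accumulated during the upward sweep; node variances are
`σ²` over the total message precision at the node. The implementation is
verified against brute-force multivariate-normal conditioning (building the
full covariance from shared path lengths) on random trees, and
cross-checked against an independent reference implementation. Zero-length
branches are rejected with a suggestion to collapse them, since they make the
GLS weights singular; a basal polytomy is treated as rooted at the basal
node.

## Correlation battery and niche width

All genome-size correlations are plain OLS (`stats::lm`) of each metric
against genome size — deliberately not phylogenetically corrected regression,
matching how such batteries are normally reported; a PGLS mode is a non-goal
for this version. `ols_fit()` reports slope, intercept, R², the F-test
p-value for zero slope, and the residual SE; a constant response yields
R² = 0 by definition. Habitat niche width is the count of distinct habitat
types per species (set semantics, duplicates ignored); species with no
habitat rows are excluded and flagged. Because R² is symmetric, the choice of
genome size as predictor only affects the reported slope.

## The synthetic-data generator

The generator exists so every stage can be tested against planted ground
truth without downloading genomes. `simulate_genome()` plants TE copies
(consensus mutated by i.i.d. per-site substitution, uniform over the three
alternative bases, no indels — so the emitted divergence is exactly the
realized fraction of changed sites), perfect or edited SSR tracts, gene
models with regular exon/intron structure, and N-gap runs, all
non-overlapping and separated by at least 1 bp of background at the
configured GC content. Background bases flanking an SSR tract are constrained
not to continue its period, so planted tracts stay maximal runs and their
coordinates are exactly recoverable. `simulate_ltr_pairs()` mutates both
copies of an ancestral LTR with per-site substitution probability
`rate × age`, giving expected pairwise divergence `k ≈ 2 r T`.
`simulate_bm_traits()` draws Gaussian increments with variance
`σ² × branch length`. `simulate_species_panel()` mimics a 14-species anuran
panel: genome sizes uniform on 1.1–6.8 Gb; repeat content rising from ~34% of
a 1.1 Gb genome to ~62% of a 6.8 Gb one (slope 0.68 Gb/Gb); SSR counts linear
in size; Gaussian noise calibrated so the population R² of each regression
hits its target (defaults 0.95 for repeat bp and 0.89 for SSR count, the
strengths typical of such panels).

What the generator does *not* emulate — and hence what passing tests do not
demonstrate about real data: TE nesting and fragmentation, indels within
repeats, CpG hypermutability, compositional heterogeneity along chromosomes,
assembly artifacts, and library-dependent consensus quality. Recovery results
on synthetic genomes certify the computations, not RepeatMasker's upstream
annotation accuracy.

All simulators use R's Mersenne-Twister with fixed normal and sampling kinds,
so one integer seed fully determines every output across platforms.

## Numerical choices and problem sizes

Degenerate inputs are errors, not silent zeros: Simpson needs `N ≥ 2`,
Shannon `N > 0`, p-distances need at least one comparable column, regressions
at least three complete pairs and non-constant x. Divergence bins are
half-open so a record at an edge lands in exactly one bin; a record at the
axis end is dropped and counted. Test and verification problem sizes were
chosen to keep the full suite fast while leaving Monte-Carlo bands tight:
oracle equivalence uses 100 random trees of up to 8 tips and 100 random 5 kb
sequences; LTR age recovery uses 200 pairs of 1 kb (±10% band); root-state
recovery 1000 replicates on a 14-tip tree (2 SE band); partition conservation
1000 random annotations. Synthetic genomes of 100–250 kb are ample for
landscape-shape recovery since shape depends on copy counts, not genome
length.

## Known limitations

* The SSR thresholds and the imperfect-extension constants are documented
  substitutes for the (unpublished) defaults of genome-survey SSR tools;
  results are comparable only under identical settings.
* Only the Jukes–Cantor correction is offered for LTR dating (K2P/HKY are
  non-goals), and solo or truncated LTRs are not handled.
* Landscapes inherit whatever overlap conventions the upstream annotation
  used; published landscapes rarely state theirs.
* The correlation battery is intentionally non-phylogenetic; effect sizes on
  related species should be interpreted accordingly.
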