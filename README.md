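# repeatscape

Comparative genomics of repeat-driven genome-size evolution, in R.

Eukaryotic genomes differ enormously in size, and in amphibians most of that
variation is carried by repetitive DNA: transposable elements (TEs),
microsatellites (SSRs) and the intergenic space they inflate. `repeatscape`
provides the full analysis battery used to dissect this on a species panel —
from parsing RepeatMasker annotations to reconstructing ancestral genome
sizes — plus a seeded synthetic-data generator so every stage is testable
against planted ground truth. It is aimed at researchers in molecular
evolution and phylogenetics who have genome assemblies, repeat annotations,
gene annotations and a species tree, and want the standard repeat-centric
comparative statistics without gluing together a dozen one-off scripts.

## What it computes

* **Repeat totals and divergence landscapes.** Per-subclass genome coverage
  from RepeatMasker `.out` files, and coverage histograms over percent
  divergence from consensus (1% bins over 0–50% by default) — the classic
  repeat landscape whose shape proxies TE age structure. Shapes are
  classified automatically: one peak at divergence ≤ 5% is *L-shaped* (a
  recent burst), two peaks *bimodal*, more *multi-peaked*.
* **TE diversity.** Treating the four interspersed subclasses (LINE, SINE,
  LTR, DNA) as species of an ecological community with occupied base pairs
  as individuals:
  Simpson `D = 1 − Σ nᵢ(nᵢ−1) / (N(N−1))` and Shannon `H = −Σ pᵢ ln pᵢ`.
* **Microsatellites.** Perfect SSRs (maximal tandem runs of primitive 1–6 bp
  motifs, default minimum repeats 12/7/5/4/4/4) and imperfect SSRs
  (seed-and-extend with match +1, mismatch −1, gap −2, minimum score 12);
  motifs standardized over rotations and reverse complement; relative
  abundance (loci/Mb) and density (bp/Mb) over the valid (non-N) length.
* **LTR insertion dating.** Global alignment of 5′/3′ LTR pairs, p-distance
  over comparable columns, Jukes–Cantor correction
  `k = −(3/4) ln(1 − 4p/3)`, and age `T = k / (2r)` with the neutral rate
  `r = 1.38 × 10⁻⁸`/site/year by default.
* **Genome partition.** Exonic/intronic/intergenic territory and assembly-gap
  tallies from GFF3 + FASTA, with exact conservation
  (exon + intron + intergenic = genome length) and per-gene intron
  enumeration across isoforms.
* **Ancestral states.** Maximum-likelihood reconstruction of continuous
  traits (genome size, TE proportion) under Brownian motion via two-pass
  message passing — each node's estimate is the GLS root estimate of the tree
  re-rooted at that node — with variances and the ML rate.
* **Correlation battery.** OLS of every panel metric against genome size
  (slope, R², F-test p), plus habitat niche width (distinct IUCN habitat
  types per species).

## Worked example

```r
library(repeatscape)

# A 200 kb synthetic genome with two planted TE cohorts (3% and 30%
# divergence) and three SSR tracts — ground truth is known exactly.
cfg <- simulation_config(
  seed = 42, genome_length = 200000,
  te_plan = data.frame(
    consensus_id = c("L1_young", "Gypsy_old"), subclass = c("LINE", "LTR"),
    copy_count = c(60, 60), target_divergence = c(3, 30),
    consensus_length = c(500, 500)),
  ssr_plan = data.frame(motif = c("A", "AC", "AAG"), repeats = c(15, 9, 6), edits = 0))
sim <- simulate_genome(cfg)

landscape <- compute_landscape(sim$repeats, genome_length = 200000)
landscape
#> <divergence_landscape> 50 bins of 1% over a 2e+05 bp genome
#>   total coverage: 30.00%; dropped records: 0 (0 bp)
#>   per subclass (%): LINE 15.00, LTR 15.00
classify_landscape_shape(landscape)
#> <landscape_shape> BIMODAL (peaks at divergence 3, 29%)
```

The two planted cohorts occupy 15% of the genome each and come back as a
bimodal landscape with peaks at their planted ages. TE diversity over the
subclass community:

```r
div <- te_diversity(sim$repeats)
sprintf("Simpson D = %.3f, Shannon H = %.3f", div$simpson, div$shannon)
#> "Simpson D = 0.500, Shannon H = 0.693"
```

Two equally abundant subclasses give exactly D = 1/2 and H = ln 2. The
planted SSR tracts are recovered at their exact coordinates:

```r
find_perfect_ssrs(sim$genome$synth1)[, c("start", "end", "motif", "repeats", "kind")]
#>    start    end motif repeats    kind
#> 1 196577 196591     A      15 PERFECT
#> 2 197741 197758    AC       9 PERFECT
#> 3 198856 198873   AAG       6 PERFECT
```

LTR dating recovers a planted insertion age from sequence divergence alone:

```r
pairs <- simulate_ltr_pairs(100, ages = 2e6, consensus_length = 1000, seed = 1)
ages <- ltr_insertion_times(pairs)
sprintf("mean recovered age: %.2f My", mean(ages$age_years) / 1e6)
#> "mean recovered age: 2.05 My"
```

And the regression battery on a simulated 14-species panel (population R²
targets 0.95 and 0.89):

```r
panel <- simulate_species_panel(14, seed = 1)
correlate_panel(panel$traits)
#>      metric  n       slope   intercept r_squared      p_value
#> 1 repeat_bp 14 627825304.7 -93601400.9 0.9585373 1.167135e-09
#> 2 ssr_count 14    529157.2    428279.1 0.9015604 2.145363e-07
```

A command-line front end wraps the same functions
(`inst/cli/repeatscape.R`), with subcommands `simulate`, `repeats`,
`landscape`, `diversity`, `ssr`, `ltr-age`, `partition`, `ancestral`,
`correlate` and `all`; every threshold is a flag, configuration files use
flat `key=value` lines, and all randomness flows from `--seed`.

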