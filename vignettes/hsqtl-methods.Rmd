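---
title: "Methods: haplotype-based QTL mapping and genetic correlation in a synthetic heterogeneous stock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-based QTL mapping and genetic correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Heterogeneous stock (HS) mice descend from eight inbred founder strains
intercrossed for more than fifty generations.  Every HS genome is a fine
mosaic of founder haplotypes, so quantitative trait loci (QTLs) map to
intervals of a few megabases, and when QTLs for two phenotypes coincide,
pleiotropy is a far more plausible explanation than linkage.  This
package implements the full analytical chain used to exploit that
property — from a phenome-wide correlation screen, through
haplotype-dosage genome scans and resampled multilocus model selection,
to interval-overlap similarity trees — together with a synthetic HS
generator with known ground truth so that every stage is testable
without animal data.

# The synthetic heterogeneous stock

`simulate_mosaics()` lays down ancestral recombination breakpoints on
each of the two haplotype tracks of each individual by a memoryless
(Poisson) process.  The mean segment length is `100/generations` cM,
converted to physical units at a fixed genome-wide 0.5 cM/Mb, so the
default 50 generations give 4 Mb segments — the fine mosaic expected of
a stock this old, without simulating pedigrees.  Founder identity at
each segment is i.i.d. uniform over the eight founders.  This
deliberately omits linkage between the two tracks, family/cage
structure, and drift in founder proportions; consequences are discussed
under *Limitations*.

All coordinates are megabases, 0-based, half-open `[start, end)`.
Half-open arithmetic makes interval unions and intersections exact:
`[10, 20)` and `[20, 30)` abut and merge to `[10, 30)` with length
exactly 20.

`simulate_phenotypes()` builds each phenotype as

> sum of QTL contributions + polygenic background + Gaussian noise,

where each QTL contribution is the founder dosage at the marker nearest
the specified position multiplied by a mean-centred founder-effect
vector, rescaled so the locus explains its stated variance fraction in
the simulated sample (total variance ≈ 1).  A locus shared between
phenotypes carries one effect vector per phenotype; the vectors are
correlated at `effect_correlation` (default 0.9).  The spec for shared
loci also admits per-phenotype variance fractions, because real shared
QTLs are rarely equally strong in both traits.  The polygenic term
spreads small random founder effects over every marker and is scaled to
`polygenic_h2` (default 0.1).

The default architecture (`default_architecture()`) mirrors the
situation the package is designed to analyse: two focal phenotypes
(`ki67`, hippocampal proliferation, and `cd8_in_cd3`, the CD8 fraction
of blood T cells) share five loci, one per chromosome; `ki67` carries
four private loci; `cd8_in_cd3` carries eight, including one 15%-variance
locus — an analogue of the major-histocompatibility-complex QTL that
dominates CD4/CD8 ratios but contributes nothing to proliferation.
QTL variance totals sit near 0.3–0.55 with `polygenic_h2 = 0.1`,
consistent with HS QTLs explaining the large majority of each trait's
heritability.

`simulate_strain_panel()` produces the two replication designs used
alongside an HS study: the eight progenitor strains with five replicate
animals each (strain value = twice the strain's own founder effect,
plus within-strain noise), and a recombinant-inbred panel of homozygous
two-founder mosaic lines (defaults: 30 lines from founders 5 and 7, the
classic B6 × DBA/2 pairing).

# Ancestry reconstruction

`infer_dosages()` reconstructs expected founder dosages from biallelic
genotypes and the founder haplotype panel with a hidden Markov model.
The hidden state is the founder pair carried by the two haplotype
tracks; transitions factorise per track with switch probability
`1 − exp(−switch_rate · d)` over `d` Mb, landing uniformly on any
founder; emissions flip each of the two allele reads independently with
probability `error_rate` (default 0.01).  The state space is
represented as an ordered pair (a K × K matrix per marker), which gives
posterior dosages identical to the unordered 36-state formulation
because emissions are symmetric in the two tracks, and reduces the
forward–backward recursion to cheap rank-one updates.  The default
`switch_rate` of 0.25/Mb equals the simulator's breakpoint density at
50 generations, so the model is well specified on synthetic data.  The
test suite checks the recursion against exhaustive enumeration of all
ancestry paths on small problems (≤ 1e-8 agreement) and confirms ≥ 0.99
posterior mass on the true founders at markers ≥ 2 Mb from any
breakpoint when founders are fully informative.

`true_dosages()` bypasses inference using the known mosaics; downstream
stages accept either tensor interchangeably.

# Genome scans

`genome_scan()` tests each marker with a partial F-test comparing
{intercept + covariates + 7 founder-dosage contrasts} to
{intercept + covariates}.  Because dosage rows sum to 2, one founder is
the reference; collinear contrasts are dropped with reduced numerator
degrees of freedom, so constant or degenerate dosage columns never
produce errors or infinite statistics.  `logP = −log10 p` is capped at
320 to keep perfect fits finite.  Missing data are removed listwise per
scan — the simplest fully reproducible choice; imputation is out of
scope.  No nuisance covariates are added by default.

`conditional_scan()` implements conditional mapping: ordinary
least-squares residuals of the phenotype on the conditioning phenotype
(complete cases), then a standard scan of the residuals.  Two facts
about this estimator shaped the test architecture.  Writing `c` for the
phenotypic correlation of the pair, the shared-locus effect on the
residual shrinks by the factor `(1 − c)/(1 + c)` in noncentrality when
the pair share their architecture symmetrically, while a private
locus's noncentrality is *inflated* by `1/(1 − c²)` because the
residual variance shrinks.  A ≥ 80% drop of shared peaks in both
directions therefore requires a strongly coupled pair (`c ≥ 2/3`),
whereas ± 20% stability of private peaks requires `c ≤ 0.41`; no single
architecture can show both.  The suite accordingly checks the
symmetric ≥ 80% attenuation on a pair whose five shared loci explain
0.75 of each trait, and private-locus stability on an asymmetric pair
in which the shared loci explain 0.65 of the conditioning trait but
only 0.1 of the scanned trait, giving an overall correlation near 0.25
— the correlation scale actually observed for the motivating pair
(about 6% of variance shared), where conditioning collapsed shared
peaks while the major-effect locus private to the T-cell trait was
untouched.  Private-locus logP is read at the causal marker, since the
windowed maximum of a weak conditioned scan is upward-biased by
neighbouring noise.

# Multilocus models and RMIP

`forward_select()` builds a multilocus model greedily: at each step the
marker with the highest conditional logP (given the selected markers'
dosages as covariates) enters if it reaches the entry threshold;
markers within 5 Mb of a selected marker become ineligible so one locus
cannot enter twice.

`rmip()` repeats the selection on `B = 100` subsamples of 80% of the
individuals drawn without replacement (subsampling avoids the
duplicated-row leverage a bootstrap would create in haplotype
regression) and reports, per 1.5 Mb genomic window, the fraction of
resampled models including a marker in the window — the resample model
inclusion probability.  An RMIP of 1 means the locus enters every
resampled model.

The entry threshold defaults to logP 2.5.  It was calibrated once, with
fixed seeds, at the package's reference null scale (one 100 Mb
chromosome, markers every 2 Mb, n = 400, B = 50,
`scripts/tune_entry_threshold.R`): across thresholds 2.0/2.5/3.0/3.5
the null call rate at RMIP ≥ 0.25 is 0.52/0.23/0.05/0.03 QTLs per scan,
and 2.5 reproduces the intended operating characteristic of about one
false-positive QTL every four null genome scans.  The false-positive
rate scales with the number of independent windows, so analyses of
much larger genomes at the same threshold will be more conservative
per window; the calibration scale is part of the package's stated
conditions.

`call_qtls()` turns a profile into QTLs: windows at or above the RMIP
threshold (default 0.25) merge when adjacent, and each QTL gets a 95%
positional confidence interval from the per-resample selected peak
positions attributed to it.  Raw 2.5–97.5 percentiles of subsample
peaks are *not* a calibrated CI: peaks from 80% subsamples of one
dataset understate the sampling variability of the full-sample peak
(in our replicates, raw percentiles covered the true position only 85%
of the time).  The interval therefore applies the standard m-out-of-n
subsampling correction — deviations from the median peak are rescaled
by `sqrt(f/(1−f))` (= 2 at f = 0.8) — and is padded by half the marker
spacing, the granularity below which a peak cannot be localised, then
widened to at least one window.  Both corrections are parameter-free.
After them, empirical coverage in the replicate study is ≈ 95–100% and
mean CI width for a single 5%-variance QTL at n = 700 is about 3 Mb,
the mapping resolution expected of a 50-generation HS.

# Interval-overlap similarity and trees

For each phenotype pair, `sorensen()` computes the length-based
Sørensen coefficient `S = 2|A∩B| / (|A| + |B|)`, where `|·|` is the
merged total megabase length of a QTL interval set and the
intersection is taken chromosome by chromosome with half-open
arithmetic.  The length-based variant is the primary one because the
quantities being compared are total lengths of QTL intervals; a
count-based variant (overlapping merged-interval counts) is available
behind `method = "count"`.  When both sets are empty, `S = 0` with a
warning — phenotypes with no detected QTLs are treated as maximally
distant rather than silently distorting the tree.  Interval arithmetic
is implemented directly on real-valued Mb coordinates (integer-based
genomic range containers would force a 1 bp lattice onto 0.1 Mb data);
a rasterised 0.1 Mb oracle in the test suite confirms agreement to
1e-9.

`group_trait_sets()` merges member phenotypes' intervals into trait-set
level sets before similarity computation, and `cluster_tree()`
agglomerates the distance `1 − S` with average linkage (UPGMA) by
default — the standard choice for similarity-derived distances; Sørensen
distance is not a metric and the clustering makes no metric assumption.
Trees serialise to Newick with cophenetic branch lengths.

# Phenome screen and strain panels

`correlation_screen()` correlates a focal phenotype with every other
phenotype, Spearman by default (average ranks for ties; p from the t
approximation at n ≥ 10 and from the exact permutation distribution
below that), Pearson optionally.  Variance explained is reported as
`100 r²` from the same method's coefficient.  The conservative
multiple-testing threshold is Bonferroni over the screened phenotype
count: `−log10(α/n)`, e.g. logP 3.29 for 97 phenotypes at α = 0.05.
`strain_panel_correlation()` evaluates panel replications at the animal
or strain-mean level — both are exposed because published panel
correlations do not always state the level — and returns the
least-squares line for scatter plots.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen once as the smallest sizes at which each property is stable:
the resolution study uses 30 replicate populations (n = 700, one
100 Mb chromosome, 1 Mb markers, B = 100); the null calibration uses
100 null scans at the reference null scale; conditional-mapping and
RMIP-specificity properties use 3–4 replicates at n = 700 on a five-
chromosome genome; enumeration and permutation oracles use toy sizes
where brute force is exact.  The full demo pipeline
(`run_pipeline()`, n = 700, five chromosomes, 16 phenotypes, B = 100)
completes in minutes on one core.

# Limitations

* No pedigree, family, cage or batch structure; no sex chromosomes; no
  dominance or epistasis.  Passing tests show the estimators behave
  correctly under the generator's assumptions, not that real HS data
  meet them.
* The breakpoint process treats the two haplotype tracks as
  independent and founder proportions as uniform; real stocks drift.
* Conditional mapping uses OLS residuals, not joint modelling; with
  strongly correlated traits the residual-variance shrinkage inflates
  private-locus significance (quantified above).
* The genetic map is a single constant (0.5 cM/Mb); recombination
  hotspots are not modelled.
* RMIP model selection is greedy forward selection; Bayesian model
  averaging and MCMC interval mapping are out of scope.
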