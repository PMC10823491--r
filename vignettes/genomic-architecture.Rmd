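---
title: "Dissecting the genomic architecture of population differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the genomic architecture of population differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genarch)
```

## The problem

When several populations are separated by geographic barriers, the genome
does not tell one story. Recombination rate, linked selection and gene flow
interact to produce a heterogeneous landscape: regions of low recombination
lose diversity to linked selection, resist introgression, and tend to retain
the deep branching signal of the species history, while high-recombination
regions are homogenized by gene flow and support discordant topologies.
`genarch` packages the window-based toolkit needed to dissect such a
landscape for a three-population system (the Tapajos, Xingu and Belem
interfluves of southeastern Amazonia, plus an outgroup), together with a
structured-coalescent simulator and simulation-trained neural networks for
demographic model selection and parameter estimation.

The system is modelled as a four-population isolation-with-migration
history. Three unrooted ingroup topologies are possible and carry fixed
labels throughout the package:

* topology 1 — (outgroup, Belem (Xingu, Tapajos))
* topology 2 — (outgroup, Tapajos (Xingu, Belem))
* topology 3 — (outgroup, Xingu (Belem, Tapajos))

Gene flow is allowed only between the geographically adjacent pairs
Tapajos–Xingu and Xingu–Belem, never Tapajos–Belem, and is parameterized in
population migrants per generation (2Nm).

## The coalescent engine

Simulation is a Hudson-style structured coalescent over a continuous locus,
written in C++ and driven entirely by R's RNG (`set.seed()` gives
bitwise-reproducible output). Lineages carry lists of ancestral segments;
events are within-deme coalescence (rate $k_i(k_i-1)/2 \cdot 1/(2N_i)$ per
generation), migration (per-lineage backward rate $2Nm/(2N_i)$), and
recombination at rate $r$ per bp on the physical span of carried material,
which yields a full ancestral recombination graph. Mutations fall on the
recorded edges under the infinite-sites model at rate
$\mu = 2.42\times10^{-9}$ per bp per generation (a passerine point estimate,
with a 1-year generation time), each at a unique position.

Demographic events follow ms-style join semantics: at the first divergence
the recent pair's ancestor occupies one deme at size `anc_recent`, and only
the migration-matrix entry between the two *surviving* demes persists.
Under topology 1 the survivors are Tapajos and Belem, which never exchange
migrants, so ancestral flow stops; under topologies 2 and 3 the
Tapajos–Xingu rate continues until the deep divergence. All flow ceases at
`t_deep`; the outgroup joins at `t_outgroup` (default $9.6$ Ma $\times$ 1-yr
generations, the fossil-calibrated split of the focal antbird's reference
species; 2.36 and 15.10 Ma are the analogous values for the other two
study systems).

Calibration is enforced by tests: $E[T_{MRCA}]$ for two lineages equals
$2N$, the mean number of pairwise differences equals $4N\mu L$ (both within
3 Monte-Carlo SE over 2,000 replicates), cross-population coalescence
without migration waits for the merge, four-gamete compatibility holds at
$r = 0$, linkage decays with physical distance at $r > 0$, and Hudson's
$F_{ST}$ decreases strictly as 2Nm runs through $\{0, 0.5, 2, 8\}$.

## Priors

The original study drew parameters from "uniform and wide" priors whose
bounds live in an unavailable supplement. The package's defaults are
therefore its own choices, with magnitudes consistent with the study's
reported estimates, and are fixed once:

| parameter | prior | unit |
|---|---|---|
| every Ne (3 extant, 2 ancestral, outgroup) | U(5e4, 2e6) | diploids |
| t_recent | U(5e4, 5e5) | generations |
| t_deep | U(max(5e4, t_recent), 2e6) | generations |
| 2Nm (each adjacent pair) | U(0, 4) | migrants/generation |
| intralocus r (single-window mode) | U(0, r_max) | /bp/generation |

`r_max` defaults to $3.021\times10^{-9}$, the largest per-species maximum
recombination rate reported by the study's recombination-map step, and is
configurable per species.

These priors matter more than any training choice. Because `t_recent` is
at most $5\times10^5$ generations while Ne ranges up to $2\times10^6$, most
draws place the bulk of coalescence in the ancestral populations. Two
consequences, measured and reported honestly by the acceptance suite:
topology classification saturates near 0.81 held-out accuracy at desk scale
(an independent random-forest baseline on the same features reaches only
~0.64, so the network is not the limit), and single-window recovery of
present-day Ne and the recent divergence time is information-limited
(a full linear model and a random forest both cap near $R^2 \approx 0.5$
for Ne). The study's published 0.93 accuracy and 0.94/0.87/0.54 $R^2$
profile evidently reflect its own prior bounds; with this package's
documented priors those values are not attainable, and the corresponding
acceptance tests record the shortfall rather than masking it.

## Summary statistics and their conventions

All statistics handle missing data with per-site sample sizes; a site needs
at least two called haplotypes in every population it involves, skipped
sites are counted, and the callable length is the sequence length minus the
skipped SNP columns (invariant positions are assumed callable).

* $\pi$ — per-site heterozygosity summed over counted sites, divided by the
  callable length.
* Watterson's $\theta_W$ — per-site harmonic correction
  $\sum_s 1/a_1(n_s) / L$, which reduces to $S/(a_1(n)L)$ without
  missingness.
* Tajima's D — standard constants evaluated at the mean sample size over
  counted sites (a documented approximation under missingness); undefined
  when $S = 0$ or fewer than 4 haplotypes.
* $D_{XY}$ and Hudson's $F_{ST}$ — ratio of sums across the window: one
  minus summed mean within-population heterozygosity over summed
  between-population diversity. The raw value is kept alongside a [0, 1]
  clamp. (A Weir–Cockerham variant was considered and dropped: the
  ratio-of-sums Hudson form is what the study's window scripts compute.)
* Patterson's D and $f_{dM}$ — frequency-based ABBA/BABA with a
  dynamic-donor denominator: when $p_2 \ge p_1$ the donor frequency
  $\max(p_2, p_3)$ replaces both $p_2$ and $p_3$; otherwise
  $\max(p_1, p_3)$ replaces $p_1$ and $p_3$ and the term is negated. The
  exact branches are pinned by a site-wise oracle in the tests.
* H-scan H — mean over haplotype pairs of the identity-tract length around
  a focal SNP, bounded by flanking mismatches (window edges otherwise) and
  truncated at inter-SNP gaps above 100 kb; pairs mismatching at the focal
  site contribute zero; physical (bp) distances throughout. Requires
  phase, and refuses pseudo-haplotypes from unphased input.

Every statistic is tested against a brute-force oracle (explicit loops over
haplotype pairs and sites) on randomized matrices with missing data.

## Windowing and the 100 kb join

The genome is analysed on two kinds of windows. Fixed-SNP windows (1,000
SNPs, at most 30% missing per SNP, trailing remainder dropped) keep the
information content constant for local PCA and window trees; fixed-length
windows (100 kb, at least 500 callable sites) are the join grid for
cross-track analyses. Variable-width tracks are regridded by
overlap-weighted averaging, which conserves the global length-weighted
mean. Quantile subsets take the upper or lower `ceiling(fraction * n)`
windows with ties broken by genomic order.

Selection-class tracks (five classes: hard, linked-hard, soft, linked-soft,
neutral) are summarized with a strict probability threshold — a window is
"assigned" only when its best class exceeds 0.70 — and the published
worked example reproduces exactly: per-species confident nonneutral
percentages 30.29, 44.83 and 54.77 average to 43.3%. The false-positive
adjustment multiplies the nonneutral fraction by $(1 - \mathrm{FPR})$,
treating every potential false positive as a neutral window classified as
selected; the study's site-level 36.8% figure is not derivable from its
main text and is deliberately not a target.

## Local PCA, MDS and corners

Per window, individuals' dosages (0/1/2; missing values mean-imputed per
site) are centred and the individual-by-individual covariance
eigen-decomposed; the top two components summarize local relatedness.
Windows are compared by the Frobenius distance between their rank-k
covariance approximations, embedded by classical MDS, and the three most
extreme regions are extracted greedily (farthest from the centroid, then
twice the point farthest from the chosen set; an exact $O(n^3)$ triple
search is available for small scans). Each corner keeps the 10% of windows
nearest its extreme point; a window may appear in more than one corner and
overlaps are reported rather than forbidden. MDS reconstructs planar
configurations to Procrustes error below $10^{-8}$, and on synthetic
genomes where one region carries different structure the embedding
separates it from the background (positive silhouette).

## Topology weighting

Window genealogies come from neighbor joining on pairwise Hamming
distances (with seeded random re-pairing of alleles for unphased input);
externally estimated trees can be supplied as Newick. For weighting, every
one-tip-per-group quartet votes for the unrooted topology given by the
four-point condition on edge-count distances, after collapsing zero-length
branches into polytomies so arbitrary resolutions of identical sequences do
not masquerade as signal. Ties split their vote equally, keeping the
weights on the simplex (a discard mode exists; the study's tool does not
document its tie rule). Exact enumeration is used up to 50,000
combinations, seeded Monte Carlo with 10,000 draws beyond that.

The end-to-end experiment simulates 200 windows of 10 kb under topology 1
with and without Xingu–Belem gene flow (2Nm = 2): without flow the mean
weight of topology 1 dominates decisively (about 0.74 against 0.12/0.15);
adding flow drags it down (about 0.29) while topology 2 rises — the
mechanism by which introgression rewrites apparent phylogenetic signal.

## Neural-network inference

Feature vectors follow the study's list: mean and variance across loci of
30 per-locus summary statistics (segregating sites, $\pi$ and $\theta_W$
per population and combined; pairwise $F_{ST}$; shared, private,
pair-private, fixed-derived and fixed-difference site counts — the count
definitions are this package's, documented in `?featurize`, since the
originals are not printed). Single-window mode uses the 30 per-window
statistics directly. Windows with fewer than 3 individuals per population
are flagged, not silently dropped. Inference simulations sample the three
ingroup populations only — no feature uses the outgroup, and the deep
outgroup branch would dominate runtime.

The networks are dense multilayer perceptrons written in base R matrix
code: 3 hidden layers of 32 rectified units; a softmax head trained with
categorical cross-entropy for classification; a single rectified output
trained with mean absolute percentage error for regression (the study's
Methods name "mean absolute percentage error (MAE)", an internal
contradiction — the spelled-out loss is used and both MAPE and MAE are
reported). Adam optimizes with a linear learning-rate decay to 1% of the
initial rate, and the percentage-error gradient is smoothed quadratically
below 1% relative error so the optimum is a true stationary point — without
these the sign-based gradient oscillates indefinitely. Features are
z-scored with constants from the training split only; zero-variance
features are dropped from both simulated and observed vectors; regression
targets are scaled by their training mean (undone at prediction) so the
rectified output starts active. Regressors train 10 independently seeded
replicates (fewer at desk scale) and predict with the replicate mean.

Goodness of fit uses the median distance from the observed vector to its
k nearest simulated vectors in standardized feature space, calibrated
against the same statistic for held-out simulated vectors, plus a PCA
overlay of the first four components.

Stratified estimation selects up to 1,000 windows per selection class
(probability > 0.70, seeded subsampling above the cap), applies the trained
single-window regressors, and reports per-class means with bootstrap
standard errors. On the synthetic landscape below, the neutral-class Ne
estimate sits several bootstrap SEs above the hard-sweep class — the
qualitative signature of linked selection dragging genome-wide demographic
estimates downward.

## The synthetic landscape

`generate_landscape()` emulates a classified genome: equal windows with a
recombination map, and a per-window selection class whose sweep-like
diversity loss is produced by multiplying every effective size of the base
model by a class multiplier (defaults 0.1 hard, 0.3 linked-hard/soft, 0.6
linked-soft, 1 neutral). This local-Ne suppression reproduces the
phenomenology needed to test stratified inference — diversity loss and
downward-biased local estimates — without simulating selection
trajectories, which is both out of scope and unnecessary for that purpose.
The emitted class-probability track puts probability 1 on the true class,
optionally blurred by a stated noise level. What passing tests on this
landscape do *not* show: behaviour under real sweep genealogies (hitchhiking
distorts the site-frequency spectrum beyond what size suppression mimics),
background selection, or misclassified windows at realistic rates.

## Desk-scale settings

Simulation counts are scaled down from the study's (which used up to one
million simulations per model): 2,500 simulations per topology with 200
loci of 10 kb and 20 haplotypes per population for the genome-wide
classifier; 2,200 recombination-aware 100 kb single-window simulations with
10 haplotypes per population for the regressors (2,000 each in the
acceptance script); 400 classifier epochs at batch 2,048 and 600 regressor
epochs with 2 replicates. The full-scale settings remain available through
`nn_config()` and the `n_sims` arguments. Measured at both 2,500 and 5,000
simulations per model, classifier accuracy is the same ~0.80–0.81 plateau,
so the desk scale is not what limits it (see Priors above).

## Numerical and degenerate-input choices

Continuous mutation positions are mapped to unique strictly increasing
integers (duplicates bumped rightward). Zero-variance PCA windows return
zero eigenvalues with a flag. The MDS of an all-zero distance matrix is
all-zero coordinates. NJ branch lengths below zero are clamped and
counted. Quartets with equal four-point sums are ties. Empty selection
classes yield NA rows, not errors. Unphased input is refused by H-scan and
randomly re-paired (seeded) for window trees. All user-facing randomness
flows through R's RNG; the four stochastic stages of training (simulation,
split, initialization, subsampling) can be seeded independently by calling
`set.seed()` before each, or jointly via the `seed` arguments.

## Known limitations

Constant per-deme sizes within epochs (no continuous growth); symmetric
default migration (a directional 4-rate option exists); infinite-sites
mutation (no multiple hits, so divergence to distant outgroups is
undercorrected); NJ window trees rather than maximum likelihood; and the
prior-bound caveat above, which is the main reason two published headline
numbers are reported as not reproduced under the package's documented
priors.
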