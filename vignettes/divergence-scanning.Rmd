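---
title: "Methods: divergence scanning, trees, LD and mixed-model association in divscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence scanning, trees, LD and mixed-model association in divscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

`divscan` compares two resequenced populations from a filtered biallelic
SNP call set onward. This vignette documents the statistical model behind
each stage, the tunable parameters and their defaults, the numerical
choices that matter for reproducibility, what the bundled simulator does
and does not emulate, and the design decisions taken where more than one
reasonable reading existed.

## Input model and site filtering

Genotypes are alt-allele dosages (0/1/2, `NA` missing) at biallelic SNPs,
with a two-label sample→population map. VCF positions stay 1-based at the
I/O boundary; internally every interval (windows, genes, sweep regions) is
0-based half-open, which makes window membership, merging and gene overlap
plain arithmetic with no off-by-one cases.

`filter_sites()` retains a site when its missing-call fraction is
*strictly* below `max_missing_frac` (default 0.10) and its minor allele
frequency is *strictly* above `min_maf` (default 0.05), both over
non-missing calls. The strictness mirrors the usual "missing < 10%,
MAF > 5%" phrasing of resequencing screens; boundary sites are removed.
When per-genotype depth is present, genotypes with `DP < min_depth`
(default 2) are masked to missing *before* the site screens. A depth rule
is ambiguous between per-site and per-genotype readings; the per-genotype
reading is the one that still has meaning downstream of variant calling,
so that is what is implemented, and it is a no-op on depth-free VCFs such
as the simulator's. Half-calls (`0/.`) are conservatively missing; phase
separators are ignored because every statistic here is dosage-based.

## Windowed diversity and F~ST~

Per site, nucleotide diversity is the unbiased pairwise heterozygosity
$\hat\pi_\ell = 2p(1-p)\,n/(n-1)$ over the $n$ non-missing chromosomes — the
fraction of chromosome pairs differing at the site. A window's π is the sum
of site values divided by the *full window size* in bp (monomorphic
positions contribute zero), matching the convention of the standard
windowed-π tools so values are per-bp and comparable across window sizes.

F~ST~ uses the Weir & Cockerham (1984) method-of-moments components
$a$ (among populations), $b$ (among individuals within populations) and
$c$ (within individuals), computed per site from the two populations'
sample sizes, allele frequencies and observed heterozygosities. Windowed
estimates are the **ratio of sums** $\sum a / \sum(a+b+c)$ over sites with
at least two genotyped diploids in each population — the weighted windowed
form, which is what the common command-line implementations report.
Negative estimates are kept as computed; clipping is a presentation choice
that would bias quantile ranking.

Windows default to 5 kb with step = window size (non-overlapping). A
"sliding window" with no stated step is read as the tool default
(step = size); overlapping windows would double-count signal in quantile
ranking. The log₂ π-ratio is directional —
`direction = c("A", "B")` means $\log_2(\pi_A/\pi_B)$ — and analyses are
intended to be run in both directions, mirroring the two one-sided scans of
a two-breed comparison. A window enters quantile ranking (`usable`) only
with ≥ `min_sites` (default 3) variant sites, both π > 0 and a defined
F~ST~: windows with zero denominator diversity would otherwise dominate the
upper tail with infinite ratios, so they are excluded and counted rather
than given a sentinel value.

## Sweep calling

`select_top_windows()` computes the upper-tail thresholds as order
statistics: the threshold is the `ceiling(q * N)`-th largest value, and
windows at or above *both* thresholds are flagged — the **intersection** of
the marginal top-q sets, i.e. the red corner of the joint F~ST~/π-ratio
scatter, not their union (the union would double the expected call rate).
With all-distinct values each marginal set has exactly `ceiling(q N)`
members; ties at a threshold are included, which is the only reproducible
choice without interpolation. Flagged windows merge when their gap is at
most `gap` bp (default 0: abutting windows merge), and a gene is assigned
to a region iff the half-open intervals share ≥ 1 bp. A gene can appear in
several regions but once in the deduplicated candidate list.

## Allele-sharing distance and neighbor joining

The per-site distance between two individuals at a biallelic site is:
identical homozygotes 0; homozygote vs heterozygote 0.5; both heterozygous
0.5; opposite homozygotes 1. In dosage terms this is $|g_i-g_j|/2$ for
homozygote pairs and 0.5 whenever either genotype is heterozygous. (The
plain $|g_i-g_j|/2$ mapping would give 0 for the het/het pair; the case
table says 0.5 — two heterozygotes share one allele on average — so the
het rule takes precedence.) The pairwise distance is the *mean* over
pairwise-complete sites: the divisor is the number of sites where both
individuals are genotyped, keeping distances in [0, 1] and comparable
across missingness patterns, where a genomic-bp divisor would make them
vanishingly small and missingness-dependent.

Trees are Saitou–Nei neighbor joining (`ape::nj`). Negative branch-length
artifacts are, by default, clamped to zero with the deficit transferred to
the adjacent branches (at the child node; through the parent node for tip
branches), preserving total tree length; `clamp_negative = FALSE` gives the
raw estimator, which the topology-recovery tests use. Bootstrap support
resamples SNP sites (columns) with replacement — the standard phylogenetic
bootstrap; resampling individuals would perturb the leaf set — rebuilding
distances and the tree per replicate and counting, for each internal
bipartition of the original tree, the replicates that contain it. Splits
are matched canonically (the side not containing the first sample), so
support is rooting-independent. Replicates are seeded and reproducible.

## LD decay

r² is the squared Pearson correlation of dosage vectors over
pairwise-complete samples (Rogers–Huff composite LD). Inputs are unphased,
and for phased data under Hardy–Weinberg the composite measure coincides
with haplotype r², so nothing is lost by not phasing. All intra-chromosomal
pairs within `max_dist` (default 300 kb) are binned by separation
(`bin_width`, default 5 kb); dense data can cap pairs per bin by seeded
uniform subsampling. The linkage-distance summary takes
`half_max = r2_max / 2` exactly and reports the midpoint of the first bin
whose mean r² is at or below it — a first-crossing rule on the discrete
curve, not an interpolation, matching how a "linked range" is usually read
off a binned decay curve. `ld_decay_scale()` additionally fits
$a e^{-d/\ell} + c$ by nonlinear least squares for a decay length.
Population subgroups are analyzed by subsetting samples before the call;
the module does not special-case groups.

## Mixed-model association

The trait model is $y = X\alpha + Z\beta + W\mu + e$: covariates and
population structure as fixed effects, one SNP effect $\beta$ per test, and
an individual polygenic effect with covariance $\sigma_g^2 K$ plus noise
$\sigma_e^2 I$. $K$ is the centered genomic relationship matrix
$\frac 1 m \sum_\ell (x_\ell-\bar x_\ell)(x_\ell-\bar x_\ell)^\top$ over
polymorphic sites, with per-site mean imputation of missing dosages (which
keeps one $K$ valid for every tested SNP). Structure enters as the top
`n_pc = 2` eigenvectors of $K$ by default — "population structure as a
fixed effect" without committing to a categorical coding, which is
available by passing an explicit design. Eigenvector signs are fixed
(largest-magnitude loading positive) so runs are bit-reproducible.

The variance ratio $\lambda = \sigma_e^2/\sigma_g^2$ is estimated by REML
once on the null model and held fixed across SNPs (the EMMAX
approximation), via a single eigendecomposition of $K$ and a deterministic
1-D search over $\log_{10}\lambda \in [-5, 5]$ (81-point grid, then local
refinement). Per SNP, generalized least squares under
$\sigma_g^2(K + \lambda I)$ gives $\hat\beta$ and its standard error, and
$\hat\beta^2/\mathrm{se}^2$ is referred to χ²(1) (two-sided Wald). The
exact single-marker REML refit is available behind `refit_per_snp = TRUE`
for cross-checks on small scans; at genome scale the approximation is
orders of magnitude faster and its calibration is verified by simulation in
the test suite. Significance is *strictly* $-\log_{10}(p) > 4$: a SNP at
exactly 4.0 is dropped. No multiple-testing layer is added beyond this
rule, matching the fixed-threshold convention; a hit at the boundary is a
deliberate non-call. Samples with missing phenotype are dropped; SNPs
monomorphic among phenotyped samples are skipped and counted.

## Expression evidence

Differential-expression tables are consumed, never computed: upstream
count modeling is a separate, well-served problem. The DEG rule is
|log₂FC| ≥ threshold (inclusive, default 2) and p < threshold (strict,
default 0.01); the candidate-gene rule relaxes these to 1 and 0.05. The
table's third column is taken as the p-value whether raw or adjusted, and
its original name is recorded, since published tables differ.
`build_evidence()` outer-joins gene identifiers from sweep scans (both
directions), per-trait GWAS hits and expression calls into a boolean
evidence table in lexicographic gene order (deterministic and
input-order-invariant).

## The simulator: what it emulates, and what it does not

`sim_config()` defaults describe a 32 + 32 two-breed design: two diploid
populations whose per-site allele frequencies follow the Balding–Nichols
model — population frequency ~ Beta$(p(1-F)/F,\,(1-p)(1-F)/F)$ around an
ancestral $p \sim U(0.05, 0.95)$ — with background divergence
`F_background = 0.1`, the mid-range of what windowed F~ST~ scans between
related livestock breeds typically average. Balding–Nichols was chosen
over a coalescent simulator because its divergence parameter is exactly
the quantity the Weir–Cockerham ratio-of-sums estimator targets (for two
equally sized populations the estimand equals F), making estimator-recovery
tests sharp rather than approximate.

Planted sweeps set a locally elevated `F_local` and then push the target
population's frequency toward the nearer boundary so that its expected
heterozygosity is divided *exactly* by the `reduction` factor
(solving $q'(1-q') = q(1-q)/R$ on the same side of ½) — a clean control on
the π-ratio signal. Linkage is generated by a first-order copy process: a
haplotype's latent frequency-quantile is copied from the previous site with
probability $e^{-\Delta/(2L)}$ and redrawn otherwise, so the allele
correlation decays with scale $2L$ and **r² decays with scale
`ld_decay_length` = L** (default 25 kb, of the order of the linkage
distances reported for livestock resequencing panels). The factor 2 in the
copy probability is deliberate: the observable being calibrated is r², not
the latent correlation. Phenotypes are causal dosage effects (relative
weights jointly rescaled so the causal component explains `h2_causal`,
default 0.2), a polygenic draw with covariance proportional to the realized
kinship scaled to `h2_background` (default 0.3), and Gaussian noise filling
the remainder; total variance is 1 in expectation. Realized effects are
written to the ground-truth sidecar.

The simulator is deliberately not a population-genetic history machine: no
recombination graph, no mutation-drift dynamics through time, no allele
frequency spectrum from demography, no genotyping error or depth
structure. Consequently, passing tests demonstrate that the estimators
recover the quantities they target under their own model assumptions —
they do not certify behavior under demographic confounding (bottlenecks,
admixture clines) or data pathologies (batch missingness, allele-balance
bias) that real call sets can show.

## Problem sizes and numerical notes

The test and acceptance simulations use desk-scale designs chosen to make
the assertions statistically sharp while staying quick: 200–400 five-kb
windows and 2000–4000 SNPs for estimator recovery and sweep calibration,
n = 200–500 for GWAS calibration/power, 200 bootstrap replicates for tree
support (support thresholds kept proportional), and ≤ 3000 pairs per bin
for LD curves. Determinism is enforced throughout: every stochastic
routine takes an explicit seed, quantile thresholds are order statistics,
eigenvector signs are fixed, and the REML search is grid-plus-refinement
rather than a stochastic optimizer. Kinship eigenvalues are floored at 0;
the REML search range $[10^{-5}, 10^5]$ covers heritabilities from ~0 to
~1 with headroom. Degenerate inputs favor explicit signaling over silent
values: all-missing MAF is a typed error distinct from a monomorphic 0,
windows without usable sites are `NA` and excluded from ranking,
sample pairs with no shared sites are an error naming the pair, and an
all-sites-removed filter result is a warning with an empty (but valid)
object.
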