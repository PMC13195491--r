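---
title: "Methods: landscape genomics of a two-lineage tree species at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape genomics of a two-lineage tree species at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oakscape)
```

## Scope

`oakscape` re-creates, at desk scale, the computational chain of a
whole-genome landscape-genomics study of a tree species split into two
deeply diverged lineages (a continental and an insular group, as in East
Asian evergreen oaks separated by the East China Sea): variant filtering
and LD pruning; invariant-site-aware windowed diversity and divergence;
runs of homozygosity and the FROH inbreeding coefficient; LD decay;
ABBA-BABA introgression tests; isolation-by-distance and by-environment;
redundancy-analysis variance partitioning; latent-factor
genotype-environment association; FST-outlier scanning; and the risk of
non-adaptedness (RONA) under projected climates. Because resequencing data
of the original scale cannot be processed on a desk machine, a synthetic
generator with known ground truth stands in for the data, and the test
suite grades estimator *recovery* rather than reproduction of field
values.

## The synthetic generator

The generator (`sim_config()`, `simulate_dataset()`) is a hierarchical
Balding-Nichols model. Each variant site draws an ancestral frequency
$p_0 \sim U(0.05, 0.95)$; each group draws
$p_g \sim \mathrm{Beta}\left(p_0\frac{1-F_g}{F_g},\,(1-p_0)\frac{1-F_g}{F_g}\right)$
with drift parameter $F_g$ (`f_group`, default 0.03 — the scale of
differentiation between the two lineages), and populations nest the same
way inside groups with `f_pop` (default 0.01, a free parameter: the
source study does not report a within-group FST matrix). Under this
model the expected ratio-of-sums Hudson FST between groups equals
`f_group` exactly in the no-substructure limit; nested population drift
adds a small positive offset (about +0.003 at the defaults), which is the
intended within-group structure, not estimator bias.

Key defaults and why:

* **Design**: 2 groups x 10 populations x 5 diploid samples (100 samples,
  20 populations) — mirroring the sampling intensity of roughly 171 trees
  from 35 populations at desk scale.
* **`invariant_fraction = 0.85`**: the share of monomorphic sites in an
  all-sites call set, taken from the ratio of non-variant to total called
  sites in resequencing data of this kind. Invariant sites are what make
  the windowed diversity estimators honest (see below).
* **Admixed contact populations** (`admix_pops = c(A10 = 0.7, B1 = 0.3)`):
  one population on each side of the divide draws its frequencies as a
  mixture of the two group frequencies before genotypes are sampled,
  emulating secondary contact across a glacial land bridge.
* **Environmental clines**: `n_adaptive = 50` variant sites receive a
  logit-scale shift `beta_env * z(env)` (default `beta_env = 1.5` per SD
  of the driving variable, bio12) — strong but plausibly polygenic local
  adaptation.
* **Linkage**: haplotypes are built by a copying chain whose latent state
  is retained between adjacent sites with probability
  $\exp(-d/\ell)$, $\ell$ = `ld_decay_bp` (default 10 kb, the scale of
  observed LD half-decay distances). Marginal frequencies are exact;
  correlation decays monotonically with distance.
* **ROH plants**: intervals in which a sample's heterozygous calls are
  forced to the locally major homozygote, giving ground truth for the
  detector.

The environment generator produces the six bioclimatic variables (bio5,
bio8, bio9, bio12, bio15, bio17) per population with *weak* latitudinal
trends and dominant local noise. This is deliberate: in the study system
isolation by environment is weak (a negative, non-significant Mantel
correlation) and the environment/geography confounded fraction of the
pRDA is tiny (0.004), so an environment strongly collinear with the
group structure would contradict the system being emulated — and would
also make conditional inference ill-posed. One collinear pair is always
planted (bio17 as a near-affine function of bio12, r > 0.8) so the
collinearity filter has real work. Future horizons shift each
population's values; the high-emission scenario (SSP585) shift is exactly
2.5 times the SSP126 shift, making genomic vulnerability monotone in
emissions by construction.

**What the generator does not emulate**: a coalescent site-frequency
spectrum (ancestral frequencies are uniform, so Tajima's D on simulated
data is positive rather than the negative values typical of expanding
populations), recombination maps, selection through time, or
sequencing-error models. Passing recovery tests therefore demonstrates
correctness of the estimators under controlled truth, not faithfulness
of any particular field estimate.

## Diversity and divergence

All within- and between-sample-set statistics are built from one counting
kernel (`site_diff_counts()`): at a site, the number of differing pairs
among the non-missing alleles and the number of comparable pairs. Per
100-kb window (non-overlapping tiling; one value per window),

$$\pi = \frac{\sum_\text{sites} n_\text{diff}}{\sum_\text{sites} n_\text{comp}},$$

a ratio of sums over *all* sites including monomorphic ones — never a
mean of per-site ratios — so that missing data and invariant sites are
weighted correctly. DXY is the same ratio with cross-group pairs. Hudson
FST is $1 - (\sum D_w/\sum C_w)/(\sum D_b/\sum C_b)$ with the within sums
pooled over both groups, computed over variant sites only; this makes the
estimate invariant to adding or removing invariant sites (asserted in the
tests), while dropping invariant sites inflates π and DXY — the reason
all-sites calling matters.

Window filters follow the study design: π/DXY are reported missing where
sites with at least one valid comparison cover less than 10% of the
window span in bp (the denominator is a package decision — the source
method names the rule but not the denominator — and is configurable);
FST is reported missing below 20 SNPs per window.

Tajima's D uses the canonical equal-sample-size constants. Missing data
are handled by complete-case restriction: within a window, segregating
sites whose non-missing allele count equals the modal count enter the
statistic; sites with fewer calls are excluded. This is an approximation
(documented, since no standard tool defines D under missingness) whose
cost is a slight loss of sites, not bias.

## ROH, FROH, LD decay

`detect_roh()` is a PLINK-style scan with every internal made an explicit
parameter: 20-SNP windows are homozygous at ≤ 1 heterozygous and ≤ 5
missing calls; a site is eligible when more than 5% of windows covering
it are homozygous; maximal eligible runs become segments if they span
≥ 10 kb, contain ≥ 50 SNPs, and are no sparser than one SNP per 50 kb.
Bit-compatibility with PLINK is not promised; rule-level fidelity is, and
a brute-force enumeration of every window and run defines correctness in
the tests. Like PLINK, the hit-rate rule lets segments extend a few SNPs
into moderately heterozygous flanks; recovery fixtures therefore use
strongly heterozygous flanks, where the extension is provably one SNP.

FROH = (summed ROH length) / Lauto with Lauto the SNP-covered span
(first to last SNP per chromosome, summed) — the genome a SNP panel can
interrogate.

LD decay uses the composite (dosage-correlation) r² over jointly
non-missing samples, binned by distance; the half-decay distance is the
linear interpolation of the first downward crossing of half the curve
maximum. Genotype r² rather than haplotype r² is used because input is
unphased; the simulator's phased haplotypes let the tests confirm the two
agree in expectation.

## Introgression

The D statistic uses the population-frequency formulation: after
polarizing each site so the outgroup carries the ancestral allele
(flipping where outgroup frequency > 0.5),
ABBA $= \sum (1-p_1)p_2p_3(1-p_o)$ and BABA $= \sum p_1(1-p_2)p_3(1-p_o)$,
$D = (\mathrm{ABBA}-\mathrm{BABA})/(\mathrm{ABBA}+\mathrm{BABA})$.
Significance is a delete-one block jackknife over contiguous site blocks
(default 500 sites, configurable; at least 20 blocks required). Trio
orientation swaps P1/P2 so D ≥ 0 (the swap recorded), and the heatmap
mapping deposits +D at (P2, P3) and −D at (P1, P3), keeping the
largest-|D| entry per cell.

Recovery tests run at the frequency level (the statistic's natural
input): planted admixture w = 0.3 at 5,000 sites gives z > 3 essentially
always, while frequencies re-estimated from ~5 diploids per population
add binomial noise that roughly halves z at this size — a real
information limit of desk-scale data, visible in the acceptance script's
genotype-based trio output.

## Landscape analyses

Genetic distance is FST/(1−FST); geography is great-circle (haversine,
radius 6371 km); environmental distance is Euclidean on standardized
retained variables. The collinearity filter iteratively breaks pairs with
|r| > 0.8, dropping the member with the larger mean absolute correlation
(ties by name). Mantel tests (vegan machinery) use Pearson correlation of
lower triangles with one-sided (greater) permutation p — the
isolation-by-distance direction; 9,999 permutations by default.

RDA is ordinary multivariate least squares: R² = fitted / total sum of
squares of the centered response (individual allele frequencies,
dosage/2, mean-imputed). Partial RDA residualizes response and predictors
on the conditioning block but keeps the *full* response total in the
denominator, so that the marginal and conditional fractions obey the
additive identities

conditional = full − other marginal, confounded = sum of marginals −
full, unexplained = 1 − full,

exactly (nested projections; asserted to 1e-12 on every run). Raw R² is
used for the identities — the printed decomposition of the source
analysis obeys raw-R² arithmetic — with adjusted R² also reported.
Permutation p-values test both marginal and conditional models, labeled
separately, since which of the two a published partial-RDA p refers to is
often ambiguous.

## Association, outliers, RONA

`gea_scan()` is a two-stage latent-factor association: per site, OLS of
dosage on the standardized environment plus latent factors, t-test on the
environment coefficient, BH correction per variable, q < 0.05 flags. The
genomic inflation factor (median χ²/0.456) is attached for calibration
checks. Latent factors are top left singular vectors of the centered,
mean-imputed dosage matrix. For a two-cluster structure the pipeline
conditions on **one** factor: K ancestral clusters span K−1 axes of a
centered genotype matrix, so "structure at K = 2" means a single ancestry
axis. This matters: with a strong polygenic cline, the second singular
vector *is* the environmental axis, and conditioning on it erases the
signal entirely; conversely, projecting the environment out of the factor
estimate (an option offered via `covariates`, as some latent-factor
methods do) leaves chance env-aligned structure uncontrolled and inflates
the null. One plain factor gives both a calibrated null (λ in [0.9, 1.15]
across null replicates) and near-complete power at the planted-cline
conditions.

The divergence-outlier stage is a Lewontin-Krakauer-style scan: per-site
Hudson FST across populations, scaled to t = (k−1)·FST/mean(FST),
referred to χ²(k−1) upper tail, BH-corrected. It is a deliberate,
documented substitution that preserves the role of a Bayesian FST-outlier
method (divergence outliers to intersect with association hits) with a
transparent, testable statistic; the output schema (site, fst, q) is
kept. Candidate sets intersect as: sites significant for ≥ 1 variable ∩
outlier sites.

RONA regresses population allele frequency on the present-day variable
across populations, per site; sites with regression p < 0.05 (the
threshold is a package decision, configurable) enter, and per population
RONA is the mean |predicted future − predicted present| frequency, with
predictions clamped to [0, 1] before differencing. It is invariant to
affine rescaling of the environmental variable, exactly zero under
unchanged climate, and monotone in the emission scenario whenever the
high-emission shift dominates uniformly (which the generator guarantees).

## Numerical and interface decisions

* MAF boundary: sites at exactly the threshold are retained (drop iff
  maf < threshold); depth masking precedes site-level missingness
  (VCFtools order); coordinates are 1-based inclusive.
* LD pruning removes, within each 50-SNP window, the member of the worst
  pair with the smaller call count (ties: larger index), sliding by 10.
* Degenerate inputs: empty allele sets give (0, 0) counts; S = 0 windows
  give missing Tajima's D (never 0); abba+baba = 0 gives undefined D;
  zero jackknife SE gives undefined z; constant environments and
  rank-deficient predictor blocks are errors that name the offender.
* Problem sizes in tests and the acceptance script (5,000-site genomes,
  100-replicate recovery runs, 1,000-trial Mantel calibration) were
  chosen so the full suite completes in minutes on one core while keeping
  Monte-Carlo error well inside the asserted bands.

## Known limitations

Tajima's D on generator output is positive (uniform ancestral
frequencies, no coalescent SFS). The copying-chain LD is a first-order
stand-in for recombination. The latent-factor association controls only
coarse (group-level) structure; population-level pseudo-replication of
the environment (env constant within populations, tested at individual
level) leaves a small residual inflation (~1.1) that the reported λ makes
visible. Frequency estimates from ~5 diploids per population limit the
power of the D statistic at desk scale. None of these affect the
closed-form contracts (variance-partition identities, RONA arithmetic,
FST transforms), which hold to machine precision.
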