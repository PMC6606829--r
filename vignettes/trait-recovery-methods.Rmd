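---
title: "Growth-trait recovery from metagenomic time series: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-trait recovery from metagenomic time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sludgecycle` estimates two growth traits — rRNA operon (*rrn*) copy
number and the in situ replication index — for metagenome-assembled
genomes (MAGs) observed across a long biweekly time series, and relates
them to disturbed versus stable operational periods identified from the
community itself. This vignette explains the underlying models, the
tunable parameters, the synthetic community that the test suite uses as
ground truth, and the numerical decisions that were genuinely open.

## The coverage model

All inputs are mean per-base read depths ("coverage", x-fold). Coverage
of a genome is proportional to its cell abundance times sequencing
depth; coverage of a multi-copy gene is that of its genome times the
copy number. Two consequences drive the estimators:

* the ratio cov(16S)/cov(genome) estimates the *rrn* copy number per
  genome, independently of whether the operon assembled into the MAG;
* along a replicating chromosome, coverage decays from the single
  replication origin to the terminus, and the peak-to-trough ratio (PTR)
  of that gradient reflects the fraction of cells caught replicating.

## MA16S–MAG matching

A reconstructed 16S sequence (MA16S, admitted at ≥ 900 nt) is paired to
a MAG only when four lines of evidence agree: Pearson correlation of the
two raw coverage profiles over the whole series (r > 0.7 with two-sided
p < 0.001 from the t distribution on n − 2 df), taxonomic concordance at
the deepest rank both lineages resolve (missing ranks never conflict),
and at least one physical link — a BLAST hit from the MA16S to a member
contig at identity ≥ 98 %, alignment > 100 nt and fewer than 5
mismatches, or paired-end reads connecting the MA16S to member contigs
(≥ 5 pairs in total). Requiring *both* physical lines is available via
`require_both`, but consensus-reconstructed 16S sequences do not always
match assembled contigs at 98 % even for true pairs, so the default is
the disjunction. Pearson is computed on raw coverages, not logs: the
pairing signal is the proportionality of absolute profiles.

Surviving candidates are reduced to a one-to-one pairing greedily by
descending r, and displaced candidates are reported as conflicts. The
one-to-one rule is a package convention; genomes genuinely carrying two
divergent 16S variants would need a relaxation of it.

## rrn copy numbers

For each accepted pair, the per-sample coverage ratio is taken in every
sample where the MAG coverage exceeds 1 (ratios at lower coverage are
dominated by mapping noise), the arithmetic mean of those ratios is the
raw estimate (the median is reported alongside for robustness), and the
integer copy number is `max(1, round(mean))`. At least 5 usable samples
are required; estimates with fewer are flagged rather than dropped
silently. The metagenome-wide variant divides the summed coverage of all
MA16S by the coverage of each of 13 single-copy universal marker genes
and reports the per-sample median across markers; it needs no MAG
matching and therefore cross-checks the per-MAG route against selection
bias in which genomes were binned and matched. On synthetic communities
where *all* genomes are matched the two estimators agree within ~10 %
in every sample; on real data, decoy SSU sequences (from organisms
without a matched genome) inflate the metagenome-wide numerator, which
is precisely why the comparison is informative.

The community-level trait is the abundance-weighted mean copy number
`W_s = Σ a_gs c_g / Σ a_gs`, computed per sample over the MAGs that have
estimates (a flag controls whether the abundance denominator is
restricted to those MAGs; restricting is the default since unmatched
MAGs contribute no copy information).

## The replication index and its noise model

Window order is unknown for draft genomes, so the estimator sees only
the *multiset* of window coverages. Writing d ∈ [0, 1] for the relative
origin→terminus distance, the model for log2 window coverage is
Uniform(a, a + s) — the log-linear gradient with span s = log2 PTR —
convolved with Gaussian window noise of unknown scale. The classical
recipe (sort windows, trim 5 % per tail, regress log2 coverage on
equally spaced abscissae, report 2^range) is retained for its r²
diagnostic (admission requires r² ≥ 0.90) and as `method = "quantile"`,
but it has a structural bias: the spread of the sorted values includes
the noise quantile spread, so a non-replicating population with 5 %
window noise yields ≈ 2^(3.4·σ) ≈ 1.17 rather than 1. The default
estimator therefore fits the convolution model by maximum likelihood
(L-BFGS-B over location, span and noise scale) and compares it against
the no-gradient Gaussian model by BIC; when the no-gradient model wins,
the index is exactly 1. In the trimmed fit the trimmed windows keep
their positions on [0, 1], so the fitted range extrapolates to the full
origin→terminus span; re-spacing the trimmed subset would shrink every
estimate by the trimmed fraction. The ML fit uses the *untrimmed* sorted
values because the likelihood would be misspecified on a truncated
sample.

The identifiability limit is real: when s is below roughly three times
the per-window noise scale, the convolution is statistically close to a
Gaussian and the BIC gate snaps the estimate to 1. With 2000 windows and
5 % window noise this affects PTR below about 1.2; the admission
filters (coverage > 5) and the window construction of sliding 5-kb
windows (whose averaging keeps per-window noise small) are what make
the regime of interest identifiable.

Genome admission follows strict inequalities: fewer than 175 scaffolds
per Mbp, completeness above 75 (75.0 exactly is rejected), contamination
below 5, mean coverage above 5.

## Local similarity analysis

Each abundance series is normal-scored (z_i = Φ⁻¹(rank_i/(n+1)),
midranks for ties). The local similarity statistic is a dynamic program
over aligned positions with offset at most D: running sums of
elementwise products, reset at zero, for both signs; the best segment
sum divided by n is the score, and the offset of the maximizing
alignment is the delay (ties prefer smaller |delay|, then positive).
D defaults to 3 samples (six weeks at the biweekly cadence); the
equivalence of the DP with exhaustive segment enumeration is tested at
small n. Significance is two-sided on |score| by permutation of one
series, p = (1 + #{null ≥ observed})/(1 + n_perm), with one shared set
of n_perm = 1000 shuffles across all pairs of a screen and
Benjamini–Hochberg q-values over the screen. Features enter the screen
when their mean relative abundance strictly exceeds 0.05 %. Edges with
|score| > 0.6 and q < 0.01 form the network (a raw-p mode exists because
figure-caption conventions sometimes quote P rather than q); the k-core
with k = 10 on positive edges isolates densely co-occurring guilds and
their summed relative-abundance series.

## SOM consensus periods

Samples are clustered twice on 5×5 grids: from MAG abundances and from
functional-module abundances. Both matrices are log-transformed (half
the smallest positive value as pseudocount) and per-feature z-scored:
abundances span orders of magnitude, and on the raw scale the abundant
features dominate the distance and make within-cluster spread
heteroscedastic. Training is *batch* Kohonen with a Gaussian
neighborhood whose radius decays linearly from half the grid diagonal
to 1; prototypes are initialized on the first two principal axes with a
fixed sign convention, so training is deterministic and invariant to
sample order without consuming randomness (a stochastic online SOM
would reproduce prototypes only distributionally; partitions are what
the analysis consumes). Prototypes are cut by Ward's minimum-variance
method into k = 3 superclusters for the MAG view and k = 4 for the
module view — the module view resolves one extra functional period, and
both k are exposed as arguments. Superclusters are matched across views
greedily by Jaccard overlap of their sample sets, the consensus set of a
matched pair is the intersection, and the two largest disjoint consensus
sets are the candidate periods, labeled by majority regime when a key is
supplied. Transition samples do not survive as a large consensus set
because the two views partition them differently — in the generator this
is guaranteed by giving the module matrix its own temporal changepoint
(below).

Two-group feature screens (STAMP-style) use Welch's t with
Welch–Satterthwaite degrees of freedom and BH correction at 0.01.

## The synthetic community

`simulate_community()` is the ground truth for every recovery test. Its
defaults emulate the study design the package targets: 60 biweekly
samples; a disturbed period at samples 10–25 (16 samples) and a stable
period at samples 42–58 (17); 173 genomes by default with copy numbers
1–8 skewed toward 1–2; total genome depth 400× per sample; lognormal
multiplicative coverage noise with cv 0.10 (coverage tables are
real-valued means, so lognormal rather than Poisson). Genomes carry a
regime affinity; matching the sample's regime multiplies abundance by 8,
mismatching by 1/8 — enough to produce cleanly separable anti-phased
guilds without making coverage-profile matching trivial. Transition
samples receive a random intermediate disturbance intensity in
(0.35, 0.65), applied as a power of the boost: operational transitions
are heterogeneous in-between states, not a third archetype, and this is
what lets the SOM views agree on the disturbed/stable periods while
disagreeing on the transitions. The module matrix follows the summed
abundance of each affinity guild for regime-linked modules, while the
remaining third of modules carry a sharp mid-series functional
changeover (a logistic step, motivated by a progressing plant upgrade),
splitting the transition samples into early and late functional states.

Window profiles place windows on an equally spaced origin→terminus grid
(so the noiseless max/min ratio equals the PTR exactly) and use their
own noise scale, 5 % by default — window coverages average thousands of
positions, so their noise is smaller than contig-level sample noise.
True PTRs are drawn from Normal(1.57, 0.14) clamped to [1, 4],
independent of regime by default; `ptr_link_regime` imprints a
regime-linked alternative for power analyses. Amplicon counts are
multinomial draws with probabilities ∝ abundance × copy number,
reproducing the classical amplicon copy-number bias. Decoy 16S profiles
are independent lognormals — the hardest plausible negative for
correlation matching — and receive only sub-threshold support evidence
(identity 90–97 or fewer than 5 read pairs). Baseline abundances are
lognormal with sd(log) 0.8 by default; the copy-number recovery fixture
in the tests uses 0.5 so that every genome clears the coverage-1 ratio
admission in 60 samples — recovery is then a property of the estimator,
not of which genomes happen to be observable.

What the generator does *not* emulate: GC bias and mappability
artifacts, assembly chimerism, strain mixtures within a MAG, genomes
with divergent intra-genome 16S copies, and compositional coupling
beyond the closure of relative abundances. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
noise model, not robustness to assembly pathology; the GC-correction
hook of the replication-index module is reserved for real-data use.

## Problem sizes and test design

The suite exercises the study's geometry (60 samples, 16/17 consensus
split) at reduced community sizes: 40-genome fixtures for copy-number,
matching and consensus recovery (20 seeds each), 34 OTUs for the
two-guild network, 2000-window profiles for the PTR sweep, and a
30-genome, 5-genome-profiled fixture replicated 30–60 times for the
joint trait pattern (the disturbed-vs-stable replication comparison is a
calibrated 5 % test under the null, so its non-significance rate is
estimated from enough replicates that sampling variation does not
dominate). Permutation counts are 1000 for screens and 200–500 inside
fast tests. Statistical assertions use margins consistent with the
binomial noise of those replicate counts.

## Known limitations

* The one-to-one matching rule cannot represent genomes with two
  divergent 16S variants.
* The replication index is reported as 1 whenever the gradient is not
  BIC-identifiable against window noise; very slow replication (PTR
  < ~1.2 at 5 % noise) is indistinguishable from none, and published
  sorted-fit implementations would instead report a noise floor above 1.
* The metagenome-wide copy-number estimate includes all SSU sequences in
  its numerator; on real data its agreement with the MAG-wise estimate
  degrades exactly as unmatched organisms become abundant — a documented
  diagnostic, not a defect.
* The command surface is the exported functions plus `run_pipeline()`
  with a YAML config; no shell entry point is shipped, as the package is
  meant to be driven from R.
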