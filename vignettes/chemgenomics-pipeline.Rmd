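---
title: "Methods: pooled deletion-library fitness profiling with chemgenfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled deletion-library fitness profiling with chemgenfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemgenfit)
```

## The experiment being modeled

A pooled library of barcoded deletion strains — one unique up-tag barcode per
deleted gene — is inoculated into medium containing a single chemical
inhibitor at a dose chosen to inhibit roughly 30% of wild-type growth, next
to an in-plate control culture of the same pool in inhibitor-free medium.
After serial growth totalling roughly 6.5–10 population doublings, barcodes
are amplified and sequenced; a strain's read fraction measures its relative
abundance. Each treatment replicate is paired with its in-plate control, in
biological triplicate; a few compounds (suspensions whose in-plate controls
are unusable) are analyzed unpaired against a pool of control samples.

The quantity of interest per gene and inhibitor is the log2 ratio of
normalized abundance in inhibitor versus control: positive values mean the
deletion is beneficial under that inhibitor, negative deleterious. Downstream
the package asks three questions: which deletions matter for which compounds
(differential fitness), how often a deletion helps under some compounds and
hurts under others (antagonistic selectional pleiotropy), and which compounds
and gene modules behave alike (profile correlation, mixture clustering,
signed functional enrichment).

## The competition and count model

The generator propagates expected strain frequencies deterministically:
after $G$ doublings, strain $g$'s abundance under compound $c$ is
proportional to $p_{0,g}\,2^{G(1+s_{gc})}$, where $s_{gc}$ is the planted
per-doubling log2 growth-rate deviation (selection coefficient) and $s = 0$
in controls. The factor $2^G$ cancels in the treatment/control contrast, so
the planted log2 abundance change is exactly $G\,s_{gc}$ — a closed form the
tests use as an oracle. We chose deterministic propagation (no stochastic
drift between passages) precisely to keep that closed form; drift in a pool
of $\sim 10^6$ cells per strain is negligible at these scales.

Reads are then drawn gamma-multinomially: each sample multiplies its expected
fractions by per-gene gamma weights with mean 1 and variance $\phi_g$ before
a single multinomial draw of the library size, giving negative-binomial-like
overdispersion $\phi_g$. A treatment sample and its paired control share a
replicate-level sequencing depth and a per-gene log-normal batch effect
(σ = 0.3 by default), which is what makes the paired fitness test demonstrably
more powerful than an unpaired one on the same data. All random draws happen
before any multinomial sampling, so changing only the depth changes only the
final read noise — another property the tests rely on.

Defaults: dispersion 0.05 and depth 2×10⁶ reads/sample (typical bar-seq
scale at desk-friendly runtime); per-sample read depths and dispersions are
not published for the motivating dataset, so these are stated choices, not
estimates. Initial pool frequencies are mildly variable (gamma-distributed,
CV ≈ 0.32) rather than exactly uniform, as real pools are.

### Planted structure

Gene classes default to 70% neutral, 10% beneficial-only, 10%
deleterious-only, 10% antagonistic, allocated deterministically so requested
fractions are exact. Compounds are grouped into classes; a non-neutral gene
is active in each compound class with probability `p_active` (antagonistic
genes in at least two, with mixed signs — which is why they require at least
two compounds). Within an active class the gene carries one base magnitude
|s| ~ U[0.1, 0.5] per doubling, signed by its class, with per-compound
multiplicative jitter U[1−a, 1+a] where $a=\sqrt{3(1/r-1)}$ calibrates the
within-class Pearson correlation of true effect columns to the requested
$r$ (default 0.9). Between-class correlations are small but not zero
(single-signed genes active in several classes contribute positively,
antagonistic genes negatively), which is also true of real compound panels.

## Differential fitness

Counts are TMM-normalized: each sample is compared with a reference (the
sample whose upper-quartile count proportion is closest to the panel mean);
per-gene M-values are trimmed 30% from each tail by M and 5% by A, and the
factor is 2 to the weighted (inverse asymptotic variance) mean of the
surviving M-values, rescaled to geometric mean 1. These trim conventions are
the field standard — the motivating analysis names the method but not its
parameters. Our implementation is checked against both a brute-force oracle
and edgeR's `calcNormFactors` (agreement to 1e-12).

Each inhibitor is fit as a negative-binomial log-linear model with log
effective-library-size offsets, dispersion estimated by adjusted profile
likelihood with empirical-Bayes shrinkage toward a trend, and the treatment
coefficient tested by a quasi-likelihood F-test with squeezed residual
variances — the edgeR `estimateDisp`/`glmQLFit(legacy = TRUE)`/`glmQLFTest`
stack, which is also what the motivating study used. The paired design is
pair-block factors plus a treatment indicator (with three pairs: two residual
degrees of freedom); unpaired compounds use intercept + treatment against the
unpaired control pool. Log fold-changes are stabilized with a prior count of
0.5; genes with zero counts across a contrast are untestable and reported NA.

BH adjustment is applied within each inhibitor (the analysis reports
per-inhibitor significant-gene counts; a pooled alternative is exposed via
`global_fdr = TRUE`), with NA p-values excluded from the number of tests.
Significance is q < 0.05. On null simulations at the default design the
observed type-I error at α = 0.05 is ≈ 0.046–0.048 (the acceptance suite
asserts [0.025, 0.10]) and essentially nothing passes q < 0.05.

## Antagonism statistics

Per gene, the package counts inhibitors with significant beneficial and
deleterious effects; the beneficial proportion divides by significant
conditions only. A gene is antagonistic iff it has at least one significant
effect in each direction. The pairwise antagonistic proportion for
inhibitors (i, j) divides the number of antagonist genes by the union of
genes significant in i or j. The default antagonist rule requires
significance in **both** inhibitors with opposite signs — the stricter
reading; because the original rule is ambiguous, `rule = "union-signed"`
(significant in at least one, opposite-signed point estimates) is also
implemented. Exclusive intersections against a focal inhibitor follow UpSet
semantics: each gene counts toward exactly the subset pattern matching its
full membership, so the exclusive sizes sum to the union size exactly.

## Profiles and clustering

Inhibitors are classified by Pearson correlation of their log2 effect
columns over the significant-union genes, using pairwise-complete rows, then
average-linkage hierarchical clustering on 1 − r. Partitioning the resulting
tree into named compound classes is deliberately left to the analyst (the
original boundaries were drawn manually); the package emits the matrix,
merge heights, and a Newick tree.

Gene profiles are clustered with a k-component Gaussian mixture sharing one
isotropic covariance σ²I (the spherical, equal-volume EII family), fit by EM
with k-means++-style seeding, best of `n_starts` runs by final
log-likelihood, hard assignment by maximum responsibility, and convergence
when the log-likelihood gain drops below `tol` (1e-6). σ² is floored at
1e-8. The log-likelihood trace is non-decreasing (asserted in tests); should
a component empty, it is re-seeded at the worst-explained point, which
restarts the ascent and is reported. Missing log2 effects (genes untestable
for some inhibitors) are imputed as 0 before clustering — no fitness effect
is the natural neutral value, and the original handling is unstated. At
study scale the analysis uses k = 50; the package leaves k a parameter.
Within each cluster genes are ordered by average-linkage clustering on
1 − Pearson (undefined correlations get the maximal distance 2; ties resolve
by input order), and the reordered matrix is exported as a CDT readable by
TreeView-style viewers, round-tripping bit-exactly through the package's own
reader.

## Enrichment

Beneficial and deleterious significant lists are tested separately against
each gene set with the exact hypergeometric upper tail; significance is
p ≤ 1e-4 with **no** multiplicity correction — functional categories overlap
heavily, and a stringent fixed cutoff avoids the resulting over-correction.
The default universe is the genes tested for that inhibitor (conditioning on
testability; `all` and `union` are exposed). Diagnostic gene sets are derived
from a reference compendium of compound × gene z-scores grouped into response
signature sets: a gene joins the positive (negative) list of signature set S
if its compounds with z > 3.09 (z < −3.09) concentrate in S by upper-tail
hypergeometric test at p ≤ 1e-3. The association cutoff is ours (the source
analysis states the z threshold only), as is the per-gene compound-count
formulation of the test; a pooled-event formulation would also be defensible
but conditions less sharply on each gene. The signed matrix keeps
category × inhibitor cells at p ≤ cutoff, scored ±(−log10 p) (positive =
beneficial-list), keeping the smaller p when both directions qualify (exact
ties score 0 and are flagged), and clusters rows and columns with Euclidean
average linkage.

## Growth curves

AUC is the trapezoidal integral of OD600 over the recorded span. ICx
interpolates linearly in log10 dose to the (100 − x)% of-control level after
isotonic projection to a non-increasing dose-response (flagged when it
changes anything); log-dose interpolation is the standard dose-response
convention — the original only says "estimated". Doubling time is
ln 2 / slope of the sliding window (default 10 points) of ln OD with the
highest R² among positive-slope windows, requiring R² ≥ 0.98 ("exponential
phase" is not operationally defined in the source, so the window rule is
ours); mutant doubling times are normalized to the mean wild-type doubling
time of the same batch.

## Problem sizes, determinism, and what the tests do and do not show

Every generator and the EM are bit-reproducible for a fixed seed; seeded
functions save and restore the caller's RNG state. The pipeline writes a
manifest with MD5s of all outputs, and rerunning an unchanged configuration
is byte-identical.

The test and acceptance suites run at desk scale: null calibration uses 20
replicates of 2000 genes × 6 compounds × 3 pairs; recovery uses planted
changes of ≥ 2 log2 units at dispersion 0.05 and depth 2×10⁶;
antagonistic-fraction recovery uses 20 replicates per planted fraction;
oracle equivalence uses ≥ 100 randomized small instances per statistic.
These sizes were chosen as the smallest at which the binomial/statistical
bounds being asserted are meaningful.

Passing tests show the machinery is correct under the generator's
assumptions. The generator deliberately omits several features of real
bar-seq data: PCR jackpotting and chimeras, index hopping, down-tag barcodes,
plate-position effects beyond a scalar batch term, strain extinction and
drift during growth, and barcode-specific amplification bias. Conclusions
about real data still require the usual diagnostics (library-size and
dispersion plots, control-control contrasts). Headline counts from the
motivating study (thousands of significant genes across 34 inhibitors)
depend on its deposited sequencing data and are not reproducible from
synthetic data; the package instead verifies the properties that make such
counts trustworthy: calibration, recovery, sign fidelity, and exactness of
the combinatorial statistics.

## Known limitations

* The quasi-likelihood machinery is edgeR's; other implementations of the
  same model will differ in the tails (exact numerical replication of any
  specific external tool is a non-goal).
* EM finds local optima; `n_starts` mitigates but does not eliminate this,
  and k is user-chosen (no BIC model selection, EII only).
* `count_uptags` handles substitutions only — no indel alignment, adapter
  scanning, or quality filtering; the barcode position is a fixed offset.
* Isotonic ICx smoothing can mask genuinely non-monotone dose responses;
  inspect flagged curves.
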