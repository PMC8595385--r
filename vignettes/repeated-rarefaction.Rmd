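---
title: "Repeated rarefaction: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeated rarefaction: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarebands)
```

## The sampling model

An amplicon library is a vector of read counts $n_1, \dots, n_k$ over
features (ASVs/OTUs) with library size $N = \sum_i n_i$. Rarefying to a
depth $d \le N$ **without replacement** draws a uniformly random subset of
$d$ of the $N$ observed reads; the resulting count vector follows the
multivariate hypergeometric distribution with parameters $(n_1, \dots,
n_k; d)$, so no feature can exceed its observed count. Rarefying **with
replacement** draws $d$ reads multinomially at the observed proportions
$p_i = n_i / N$; a rare feature can then appear more often than it was
observed. Without replacement answers the question actually posed by
normalization — *what would this sample have looked like had only $d$
reads been obtained?* — and is the default.

A single rarefaction is one draw from that distribution: any statistic
computed from it inherits an unreported subsampling error. Repeating the
draw $R$ times (default $R = 1000$) turns every downstream statistic into
an empirical distribution, summarized as a *band* (alpha diversity per
sample and depth) or a *patch* (the sample's replicate points in one joint
ordination).

The without-replacement sampler draws features sequentially: conditional
on the reads already allocated, feature $i$'s count is univariate
hypergeometric in the remaining pool. This is exact (the joint law is the
multivariate hypergeometric), costs $O(k)$ per draw, and never
materializes the expanded read vector. Two shortcuts apply verbatim: when
the remaining demand is zero the tail is zero, and when the remaining
demand equals the remaining pool the tail is taken wholesale — both are
the exact conditional distributions in those states.

## Diversity metrics

Alpha diversity is evaluated per rarefied profile: the Shannon index
$H = -\sum_{p_i > 0} p_i \ln p_i$ (natural log, so $\exp H$ is the Hill
number of order 1) and Hill numbers
$^qD = (\sum p_i^q)^{1/(1-q)}$ with the exact branch $^1D = e^H$ at
$q = 1$; $q = 0$ is richness, $q = 2$ the inverse Simpson index. The
package reports $q \in \{0, 1, 2\}$ by default, covering the
richness-to-dominance gradient. Chao1 is deliberately absent: it needs
singleton counts, which denoising pipelines typically remove.

Beta diversity pools all $(\text{sample} \times \text{repetition})$
profiles into one distance matrix so that every replicate point lives in a
single common ordination space — overlayable patches with no Procrustes
alignment step and no alignment artifacts. The default analysis is
Bray–Curtis on Hellinger-transformed profiles ($h_i = \sqrt{p_i}$,
applied to each rarefied replicate, countering the arch effect);
Bray–Curtis on raw counts and presence/absence Jaccard are alternatives.

Ordination is classical scaling (principal-coordinate analysis): Gower
double-centering of $-\tfrac12 D^2$, eigen-decomposition, coordinates
scaled by the square roots of the positive eigenvalues. Bray–Curtis is a
semimetric, so negative eigenvalues occur; they are counted, reported, and
excluded from the explained-variance denominator (a Cailliez correction is
available behind `correction = "cailliez"`). Axis signs are fixed by
making each axis's largest-magnitude coordinate positive. Points with
identical dissimilarity profiles are snapped to identical coordinates —
they are mathematically coincident, and snapping removes eigen-solver
rounding so an unrarefied sample's patch has dispersion exactly zero.

`patchDispersion()` condenses a patch to the mean Euclidean distance of a
sample's replicate points to their centroid in the retained axes: a scalar
for "how much noise did rarefying inject into this sample's position".

## Choosing the depth

`rarefactionCurve()` draws empirical curves; `expectedRichness()` gives
their exact mean, $E[\text{richness}] = \sum_i [1 - \binom{N-n_i}{d} /
\binom{N}{d}]$, evaluated in log-gamma arithmetic to avoid overflow.
`suggestDepths()` tabulates each sample's library size as a candidate
depth together with the samples it would drop. The sensible default is the
smallest library size (drops nothing, rarefies least); when small samples
force an uncomfortably low depth, run the analysis at both an inclusive
small depth and a larger depth that excludes them, and compare.

## Random-number discipline

Every $(\text{rep}, \text{sample})$ draw uses a private substream seeded
by a multiplicative-congruential hash (modulus $2^{31}-1$, multiplier
48271) of `(seed, rep index, sample's column index in the input table)`.
Consequences: ensembles are bit-identical across runs and across
`workers` settings; within a sample, distinct repetitions can never
collide (the hash is injective in the rep index for fixed sample); and a
retained sample's draws do not change when other samples are dropped as
undersized. Functions that seed internally save and restore the caller's
RNG state.

## The synthetic generator

`generateCommunity()` builds per-sample true compositions from a
rank-abundance model (geometric series by default — the classic
long-tailed shape under which rarefaction's suppression of rare features
is visible; uniform and Dirichlet alternatives) and draws counts
multinomially at the requested library sizes (`exactTotals = TRUE`, so
column sums match the request exactly; `exactTotals = FALSE` switches to
independent Poisson counts whose totals merely center on the request).
Group structure permutes a chosen fraction of feature identities between
groups, separating their compositions.

`paperlikeCommunity()` is the standing six-sample test community: samples
A–F over a 1000-feature pool, geometric ratios 0.004–0.10 (so Shannon
diversity declines from A to F), two groups (A–C vs D–F, half the feature
identities permuted), library sizes 35,712 down to 11,213. The minimum of
11,213 reads makes depths of 5,000 / 1,000 / 500 / 100 retain all six
samples while rarefying everything except F at the full depth — the
configuration in which the package's qualitative guarantees (Shannon means
non-increasing and bands non-decreasing as depth shrinks; ordination
patches spreading; the minimum sample's patch collapsing to a point at
full depth; with-replacement Shannon slightly below without-replacement)
are asserted by the test suite at $R = 100$–$1000$ repetitions and, for
the sampling-law checks, 100,000 draws on toy libraries where the exact
distribution is enumerable.

What the generator does **not** emulate: taxonomic structure, sequence
errors and chimeras, PCR/primer bias, overdispersion between biological
replicates, and the zero-inflation patterns of real surveys. Tests passing
on it therefore validate the *subsampling machinery and its statistics*,
not any ecological claim about real communities.

## Numerical and design notes

- Counts are validated as non-negative integers at construction; nothing
  is silently rounded. Proportions and transforms exist only downstream.
- Taxonomy exclusion (`filterByTaxonomy()`, default terms mitochondria and
  chloroplast) is a case-insensitive substring match on the whole lineage
  string, robust to rank-prefix differences between databases; features
  without annotation are retained, since an exclusion list names what to
  remove.
- Library-size ties take the first sample in column order.
- Band bounds default to the 2.5–97.5% empirical quantiles
  (`stats::quantile` type 7, linear interpolation); they are descriptive
  envelopes, not confidence intervals.
- Undersized samples are dropped with a warning by default
  (`undersized = "error"` to fail instead); dropping is recorded in the
  ensemble.
- `alphaOverEnsemble` computes metrics column-wise on the profile matrix;
  $0 \ln 0$ terms are dropped via `NaN` masking, equivalent to restricting
  the sums to $p_i > 0$.

## Limitations

Repeated rarefaction characterizes the variability *introduced by
rarefying the observed data*; it says nothing about uncertainty in the
source community the sample was drawn from. Studies hunting very rare
variants should not rarefy at all — rare features are regularly discarded
at any depth below the full library. And at extreme depths (tens of
reads) all communities blur together: the bands and patches will show
that, which is precisely their job.
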