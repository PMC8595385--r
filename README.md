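# rarebands

Repeated rarefaction for library-size normalization of amplicon (ASV/OTU)
count tables, with diversity analyses that show the subsampling noise
instead of hiding it.

## The problem

Amplicon sequencing returns, per sample, a vector of read counts over
sequence variants; the total count (the *library size*) varies between
samples for purely technical reasons. Diversity metrics are biased by
library size — deeper libraries look richer — so libraries must be
normalized before comparison. The common fix, *rarefying*, randomly
subsamples every library down to a shared depth, but doing it **once**
discards a random subset of the data and silently injects subsampling
noise into every downstream number.

`rarebands` rarefies **repeatedly**: each sample is subsampled many times
(default 1000), either

- **without replacement** — a multivariate hypergeometric draw from the
  observed reads (a subset of the data; the statistically preferred mode), or
- **with replacement** — a multinomial draw at the observed proportions
  (can inflate a rare variant beyond its observed count),

and the whole ensemble is pushed through the analyses:

- **alpha diversity**: Shannon index `H = -Σ p_i ln p_i` and Hill numbers
  `<sup>q</sup>D = (Σ p_i^q)^{1/(1-q)}` per rarefied profile, summarized as
  mean/median and quantile **bands** per sample and depth;
- **beta diversity**: Hellinger transform `h_i = sqrt(p_i)`, Bray–Curtis
  `Σ|x_i−y_i| / Σ(x_i+y_i)` or Jaccard distances over all
  (sample × repetition) profiles pooled into one matrix, and
  principal-coordinate ordination in which each sample appears as a
  **patch** of replicate points whose spread is the rarefaction noise;
- **rarefaction curves** with their exact analytic mean,
  `E[richness] = Σ_i [1 − C(N−n_i, d)/C(N, d)]`, to guide depth choice.

## Worked example

```r
library(rarebands)

# six synthetic samples A-F of decreasing diversity; F has the smallest
# library (11,213 reads)
sim <- paperlikeCommunity(seed = 7)
librarySizes(sim$table)$minimum
#> [1] 11213

# rarefy all samples to the minimum library size, 100 times
ens <- rarefyRepeated(sim$table, depth = 11213, reps = 100, seed = 1)

# Shannon bands: mean and 2.5-97.5% envelope across repetitions
head(summarizeAlpha(alphaOverEnsemble(ens, "shannon")), 3)
#>   sample depth  metric  q     mean   median    lower    upper n_reps
#> 1      A 11213 shannon NA 6.377911 6.378319 6.363217 6.393925    100
#> 2      B 11213 shannon NA 5.910909 5.911082 5.898020 5.923749    100
#> 3      C 11213 shannon NA 5.382371 5.382599 5.367228 5.395236    100

# ordination patches: Bray-Curtis on Hellinger-transformed profiles
ord <- pcoa(ensembleDistanceMatrix(ens), nAxes = 2)
patchDispersion(ord)
#>   sample n_reps  dispersion
#> 1      A    100 0.003268000
#> 2      B    100 0.003200485
#> 3      C    100 0.003248453
#> 4      D    100 0.002419629
#> 5      E    100 0.001719620
#> 6      F    100 0.000000000
```

Sample F's dispersion is exactly 0: at the minimum library size it is not
actually rarefied, so its 100 replicate points coincide. Shrinking the
depth lowers every mean Shannon value, widens the bands, and spreads the
patches — the quantities a single rarefaction cannot show.

Plots (`plotRarefactionCurves`, `plotAlphaBands`,
`plotOrdinationPatches`) render these tables with ggplot2 and can write a
tidy TSV twin of exactly the numbers drawn. A thin command-line wrapper
(`inst/scripts/rarebands`) chains
`simulate / filter / rarefy / curve / alpha / beta / plot` from a shell.

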