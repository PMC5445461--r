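---
title: "Gene dispersion and the read count bias: models, bounds and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene dispersion and the read count bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispbias)
```

## The problem

In two-group differential expression (DE) analysis of RNA-seq counts,
highly expressed genes tend to receive larger differential scores and are
therefore called significant more often — the *read count bias* (and,
because expected count is proportional to transcript abundance times gene
length, equivalently the *gene length bias*). The bias distorts downstream
gene-set and GO analyses. It is, however, not universal: it is strong in
technical-replicate data, and largely absent in biological replicates from
unrelated individuals. `dispbias` packages the model that explains this
dichotomy, the estimators needed to observe it, and a gene-set enrichment
analysis (GSEA) engine that demonstrates its downstream consequence:
inflated false positives under sample permutation, none under the
preranked null.

## Model

Counts are modeled per gene $i$ and sample $j$ as negative binomial,
$X_{ij} \sim \mathrm{NB}(\mu_{ij}, \sigma_{ij}^2)$ with
$\sigma_{ij}^2 = \mu_{ij} + \alpha_i \mu_{ij}^2$. The dispersion
$\alpha_i$ measures extra-Poisson variability; $\alpha_i \to 0$ recovers
the Poisson model of technical replicates, while unrelated biological
replicates typically show $\alpha_i \approx 0.1$–$0.3$.

The gene score of interest is the signal-to-noise ratio on normalized
counts,
$$ SNR_i = \frac{\mu_{i1} - \mu_{i2}}{\sigma_{i1} + \sigma_{i2}}, $$
with group means $\mu_{ik}$ and standard deviations $\sigma_{ik}$. Writing
$f = \mu_{i1}/\mu_{i2} \ge 1$ for the fold change, the NB variance gives
closed-form behavior (`snr_analytic()`):

* **Poisson limit** ($\alpha = 0$):
  $SNR_i \approx \sqrt{\mu_{i1}} - \sqrt{\mu_{i2}}$ — unbounded, growing
  with the read count. This *is* the read count bias.
* **Upper bound** (`snr_upper_bound()`):
  $|SNR_i| \le \min(1/\sqrt{\alpha_i}, \sqrt{\mu_{i1}})$. Once dispersion
  is appreciable, the score of any gene — however expressed, whatever its
  fold change or length — is capped at $1/\sqrt{\alpha_i}$. The
  $\sqrt{\mu_{i1}}$ branch explains the residual "local" bias at small
  counts (below a few tens).
* **Lower bound** (`snr_lower_bound()`):
  $|SNR_i| \ge (1 - 1/\sqrt{f}) \cdot (1/\mu_{i1} + \alpha_i)^{-1/2}$, so
  the score cannot collapse either: it is pinched near the cap.
* **Coefficient ratio** (`coefficient_ratio()`): the ratio of the two
  bounds' fold-change coefficients,
  $\left(\frac{1 - 1/f}{1 + 1/f}\right) / \left(1 - 1/\sqrt{f}\right)$,
  stays within $(1, 1.21)$ for every $f > 1$ (the supremum,
  $(1 + \sqrt{2})/2 \approx 1.2071$, sits near $f \approx 5.8$), which is
  what makes the pinch tight.

A note on the envelope form of the lower bound: the chain
$1/(1/\mu_{i1} + \alpha_i) \ge \tfrac12 \min(\mu_{i1}, 1/\alpha_i)$ yields
$c(f) \cdot \min(1/\sqrt{\alpha_i}, \sqrt{\mu_{i1}})$ with
$c(f) = (1 - 1/\sqrt{f})/\sqrt{2}$. A *max* in that position is not a
lower bound (it would exceed the upper bound whenever both $\mu_{i1}$ and
$\mu_{i1}\alpha_i$ are large), which the package's grid tests document
numerically; `snr_lower_bound()` therefore returns the tight intermediate
form and the min-envelope.

```{r bounds}
snr_analytic(100, 2, 0)      # Poisson, grows with the count
snr_analytic(100, 2, 0.1)    # capped near 1/sqrt(0.1) = 3.16
max(coefficient_ratio(exp(seq(log(1.000001), log(1e6), length.out = 1e4))))
```

## What the simulator emulates

`sample_base_means()`, `inject_de()` and `simulate_counts()` generate the
synthetic datasets all downstream analyses run on. The design emulates a
deeply sequenced two-group cohort:

* **Base means**: log-normal, `meanlog = log(500)`, `sdlog = 2`,
  truncated below at 1 by rejection. This gives a heavy right tail
  spanning five orders of magnitude, comparable to the median count
  profile of a high-depth tumor cohort. Users with a real dataset can
  instead supply one mean per line in a file (`mean_source = "<path>"`),
  which is the recommended route when the low-count regime of a specific
  platform matters — see Limitations.
* **DE injection**: a configurable fraction of genes (default 30%)
  receives a fold change drawn uniformly from `[1.3, 4]`, applied to the
  test group's mean by multiplication or division with probability 1/2
  each. Non-DE genes keep fold change 1.
* **Counts**: Poisson draws at dispersion 0, otherwise `rnbinom()` with
  `size = 1/alpha`, so that the variance is exactly
  $\mu + \alpha\mu^2$. Counts are generated at the normalized scale (all
  true size factors 1); optional per-sample depth multipliers exercise
  the normalization path.
* **Depth titration**: `downsample()` applies per-entry binomial thinning
  `Binomial(X, p)`, which maps Poisson counts to Poisson counts and
  scales expected totals by `p`.
* **Gene-sets**: `make_gene_sets()` randomly partitions the universe into
  disjoint sets of near-equal size, the null collection for the
  false-positive experiment.

What it does *not* emulate: inter-gene correlation (each gene is drawn
independently, so gene-permuting nulls are exactly valid here but can be
anti-conservative on correlated real data), zero inflation and other
single-cell features, per-gene dispersion heterogeneity (a scalar
dispersion per dataset isolates the variable under study), and
library-composition effects. Passing tests therefore certify behavior
under the NB model, not under every pathology of real data.

Reproducibility: every generator takes a seed; experiment-level drivers
derive per-repeat seeds as `root_seed + repeat_index` so repeats are
independent but individually reproducible.

## Estimators

All scoring runs on counts normalized by median-of-ratios size factors
(`size_factors()`): a gene with any zero count is excluded from the
reference, geometric means are computed in log space, and an even number
of reference ratios takes the mean of the two central values.

* `snr_scores()` — the SNR above with $n-1$ standard deviations. Genes
  whose two group SDs are both zero are reported `NA` and dropped from
  rankings rather than floored; the GSEA-style variance floor
  (`sd >= 0.2 |mean|`) is available behind `variance_floor = TRUE` but
  off by default since the plain SNR is what the bounds describe.
* `t_scores()` — Welch two-sample t, for checking that the bias story is
  not an artifact of the SNR's denominator.
* `dispersion_mom()` / `dispersion_mle()` — per-gene dispersion by
  moment inversion of $v = m + \alpha m^2$ (pooled within groups with
  weights $n_k - 1$, clamped at 0) and by profile maximum likelihood
  (group sample means profiled out, bounded search on
  $\log\alpha \in [\log 10^{-8}, \log 10]$). No shrinkage across genes is
  applied — these are deliberately "naive" per-gene estimates.
* `nb_lrt()` — the naive NB likelihood-ratio test: per gene, a two-mean
  versus one-mean NB model with `log(size_factor)` offsets, the
  dispersion estimated by ML under the full model and held fixed for the
  null fit, the statistic referred to $\chi^2_1$, and BH q-values
  attached. The dispersion search is vectorized across all genes (coarse
  log grid plus two local refinements, final relative resolution about
  1%; with equal size factors the group means are exact profile MLEs,
  otherwise IRLS alternates with the dispersion update, relative
  log-likelihood tolerance $10^{-8}$). On a fixture this implementation
  matches a `MASS::glm.nb()`-based oracle to statistic correlation
  0.99999.

## Bias profiling

`bin_genes()` orders genes by mean normalized count (ties broken by gene
identifier) into bins of 1000 (by convention), records SNR quantiles
(5/25/50/75/95%) and IQR per bin, and `de_proportion_per_bin()` adds the
fraction of genes called DE per bin. `bias_trend()` reduces a chosen
channel to a Spearman rank correlation against bin index, with
`skip_first` available to set aside the smallest-count bins where the
$\sqrt{\mu}$ bound is active. The scalar trend is this package's own
summary — the bias is conventionally assessed visually — and it is
deliberately simple; see Limitations for what a rank statistic cannot
express.

## GSEA and the false-positive experiment

`enrichment_score()` implements the weighted Kolmogorov–Smirnov running
sum (hits weighted by $|s|^p$, default $p = 1$; misses by $1/(N - m)$),
evaluated only at its $2m$ candidate extrema for speed.
`sample_permute_gsea()` builds the null by relabeling samples (group
sizes preserved, SNR recomputed each time); `preranked_gsea()` permutes
gene labels against the fixed observed ranking. Both normalize ES by the
same-sign null mean (NES), take one-sided nominal p-values from the
same-sign null, and compute FDR q by the sign-stratified pooled-null NES
ratio, capped at 1. Ranking ties break by gene identifier; genes with
undefined SNR are removed from the universe first and sets emptied by
that filter are skipped with a warning. If fewer distinct relabelings
exist than requested permutations, all distinct ones are used.

`false_positive_experiment()` wires the whole pipeline together in the
null design: DE genes are *randomly scattered* (default 2-fold, half up,
half down), so no set is genuinely enriched and every significant set is
a false positive. With small dispersions (0.001–0.01) the sample-permuting
mode produces false positives en masse — a handful of large-count DE
genes can carry a set's score past a null that permutation cannot fix,
because relabeling samples does not detach scores from read counts —
while at dispersion 0.3 the $1/\sqrt{\alpha}$ cap levels the scores and
the false positives collapse. The preranked mode produces none at any
dispersion: a large score inflates random sets exactly as often as real
ones.

```{r fp, eval = FALSE}
# the headline contrast, scaled to a laptop-minute (full defaults:
# 10,000 genes, 100 sets, 1000 permutations, 10 repeats)
fp <- false_positive_experiment(
  dispersions = c(0.001, 0.3), de_fractions = 0.3,
  modes = c("sample", "preranked"), n_repeats = 3,
  n_genes = 2000, n_sets = 20, n_perm = 300, seed = 1)
fp[, c("dispersion", "mode", "mean_significant")]
```

## Numerical and design choices

* Dispersion bounds $[10^{-8}, 10]$: the lower end is numerically
  Poisson; estimates at it are reported as the bound, never negative.
* The NB log-likelihood is written with `lgamma()` so it accepts the
  non-integer values that arise after normalization; at integer counts it
  equals `dnbinom(..., log = TRUE)` exactly.
* All-zero genes: LRT statistic 0, p-value 1; genes with zero mean in
  both groups have undefined moment dispersion (`NA`).
* BH is used for all multiple-testing control, via `p.adjust()`.
* Test problem sizes: analytic claims are checked on exhaustive grids;
  simulation claims use 10,000 genes at the replicate counts named above
  (the package's standard experimental unit), with smaller fixtures in
  unit tests where only code paths are exercised.

## Known limitations

* **The naive LRT is anti-conservative at small sample sizes.** The
  per-gene ML dispersion is biased downward at $n = 14$, so null
  p-values are mildly liberal (about 9–10% below 0.05 at dispersion 0.1,
  indistinguishable from the `glm.nb()` route). This is a property of
  the unshrunken estimator the package deliberately implements; methods
  with Cox–Reid adjustment or empirical-Bayes shrinkage (edgeR, DESeq2)
  are better calibrated and better suited to real inference.
* **A rank trend cannot grade bias strength.** `bias_trend()` is
  scale-free: a weak residual power gradient (e.g. the
  $CV^2 = 1/\mu + \alpha$ convergence at large dispersion) ranks the
  same as the strong $\sqrt{\mu}$ gradient of Poisson data. With large
  fold changes and deep coverage the DE-call channel additionally
  saturates (nearly every injected DE gene is detected in every bin), so
  contrasts between dispersion regimes show up in the *magnitudes* of
  the per-bin profiles and in the SNR tail quantiles, not necessarily in
  the trend statistic. Inspect `bias_profile` columns directly — or
  lower-depth means via the file-based mean source — when quantifying
  the contrast.
* **Independent genes.** The preranked null's perfect false-positive
  control here partly reflects the simulator's independence assumption;
  on real data, inter-gene correlation can inflate gene-permuting nulls.
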