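---
title: "Model and methods behind spotmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind spotmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A spatial transcriptomics (ST) spot captures RNA from roughly 1–100 cells,
so every measured expression profile is an aggregate over a mixture of cell
types. `spotmix` estimates, for every spot, the fraction of its cells that
belong to each of a user-specified list of cell types. Unlike
reference-based deconvolution tools, it does not need a single-cell
expression reference: the only biological prior knowledge is a binary
marker signature — which genes are over-expressed in which types — plus,
optionally, a per-spot count of nuclei segmented from the matched
histology image.

## The generative model

Counts are modelled gene-by-spot over the marker genes only. Writing
$C_{gs}$ for the count of gene $g$ in spot $s$, $B_{gt} \in \{0,1\}$ for
the marker signature, $h_{st}$ for the composition of spot $s$ and $N_s$
for its number of cells,

$$
C_{gs} \sim \mathrm{NB}\!\left(N_s\,\tfrac{1-p_g}{p_g}\,\mu_{gs},\; p_g\right),
\qquad
\mu_{gs} = \sum_t h_{st}\,(\lambda_0 + B_{gt}\Lambda_{gt}),
$$

where the negative binomial $\mathrm{NB}(r, p)$ has mean $rp/(1-p)$ (so
the mean count is $N_s \mu_{gs}$), $\lambda_0$ is a base expression level
shared by all genes, $\Lambda_{gt}$ the extra expression of marker $g$ in
its type $t$, and $p_g$ a per-gene over-dispersion parameter. In base R's
convention this distribution is `dnbinom(prob = 1 - p)`.

Compositions come from a feature-allocation prior: each type is present in
each spot independently with probability $\pi_{st} \sim
\mathrm{Beta}(\alpha/t_N, 1)$, indicator $Z_{st}$; the unnormalized
abundance $\theta_{st}$ is $\mathrm{Gamma}(a, b)$ for present types and
$\mathrm{Gamma}(a_0, b_0)$ — concentrated near zero — for absent ones, and
$h_{st} = \theta_{st} / \sum_t \theta_{st}$. The concentration $\alpha$
has a direct interpretation: the expected number of distinct types per
spot is $D = t_N\alpha/(t_N+\alpha)$ (`expected_types_per_spot()`,
inverse `alpha_for_types()`). A final *dummy* type with no markers absorbs
cells of types missing from the signature; its presence indicator is held
at zero by default ("shrinkage"), letting its abundance stay in the
near-zero Gamma branch. $N_s$ has a truncated-normal prior centered at the
image-derived count $l_s$ with spread $\sigma$.

Default hyperparameters $(a, b, a_0, b_0) = (10, 1, 0.1, 1)$ keep
present-type abundances (mean 10) well separated from absent ones (mean
0.1).

## Inference

All latent variables are sampled by a Metropolis-within-Gibbs sweep
(compiled in `src/sampler.cpp`; the per-variable conditionals are exported
as plain R functions for inspection and testing):

1. $\pi_{st}$ — exact Gibbs draw from
   $\mathrm{Beta}(\alpha/t_N + Z_{st},\, 2 - Z_{st})$;
2. $Z_{st}$ — exact Gibbs draw; the two branch weights use the fully
   normalized Gamma densities. The normalizing constants $b^a/\Gamma(a)$
   and $b_0^{a_0}/\Gamma(a_0)$ differ between branches and do not cancel,
   so dropping them (an option kept as `normalized_z = FALSE`) changes the
   conditional; the normalized form is the correct one and the default;
3. $\theta_{st}$ — one Metropolis–Hastings step per spot–type entry with a
   positive truncated-normal random-walk proposal. Changing one abundance
   rescales the whole composition row, so the full spot likelihood is
   recomputed;
4. $N_s$ — MH with a *ceiling* truncated-normal proposal (integer support
   $\ge 1$), with the matching closed-form Hastings ratio;
5. $\lambda_0$ — one global MH step (flat improper prior on $(0,\infty)$);
6. $\Lambda_{gt}$ — MH per marker entry (entries with $B_{gt}=0$ never
   enter the likelihood and are pinned at 0);
7. $p_g$ — MH per gene; proposals $\ge 1$ lie outside the support and are
   rejected.

Updates within a sweep use each new value immediately. Spot-level
variables are conditionally independent across spots given the gene-level
parameters (and vice versa), so proposals are evaluated in vectorized
passes over the independent axis — mathematically identical to a
sequential scan. During burn-in, step sizes adapt every `adapt_interval`
iterations towards a 23% acceptance rate (multiplied by $1\pm\epsilon$);
adaptation never runs after burn-in, preserving the correct stationary
distribution of the retained draws. Initial values: $\Lambda$ rows start
at the mean of the gene's non-zero counts (a data-scale starting point;
half those values are the initial $\Lambda$ step sizes), $\theta \sim
\mathrm{Gamma}(a,b)$, $Z = 1$ (dummy 0), $N_s = \mathrm{round}(l_s)$,
$p_g = 0.5$, $\lambda_0 = 0.2$. The retained, thinned composition draws
are averaged within and then across chains.

### A note on scale identifiability

The likelihood is exactly invariant under
$(N_s, \lambda_0, \Lambda) \to (N_s/c,\, c\lambda_0,\, c\Lambda)$: only
$N_s \mu_{gs}$ enters it. Two things break the tie — the truncated-normal
prior on $N_s$ and its integer support. Because $\lambda_0$ and $\Lambda$
carry flat priors, their joint volume grows polynomially along this ridge,
which in practice drags $N_s$ below its prior mean and inflates
$\lambda_0$ and $\Lambda$ by a common factor. The composition estimates
are almost unaffected (they depend on $\theta$ only through
normalization), but two consequences matter:

* absolute values of $\lambda_0$, $\Lambda$ and $N_s$ should only be
  interpreted when the scale is anchored — either by fixing $N_s$
  (`fix_n = TRUE`, the "known counts" mode) or by a strong count prior;
* $\sigma$ should encode the real confidence in the cell counts. We use
  $\sigma = 1$ when the counts are trusted (noise-free synthetic priors),
  $\sigma$ equal to the noise standard deviation when it is known, and
  $\sigma = 10^3$ with a constant $l_s$ in the unknown-counts mode. Large
  $\sigma$ with small data lets the ridge drift far enough that the
  integer rounding of $N_s$ becomes a visible error source, which is why
  trusted counts deserve a small $\sigma$.

The truncated normal's spread parameter is treated as a standard
deviation throughout (the Hastings formulas use $\Phi(x/\sigma)$), which
is the only reading consistent with the update equations.

## Marker selection

`select_markers()` implements a lead-gene-driven sieve over noisy
candidate lists: (1) keep candidates expressed above level $r_K$
(default 0) in strictly more than $r_N$ spots (default 5); (2) correlate
each survivor with the type's lead gene across spots, with Kendall's
$\tau$-b (tie-corrected — count data are tie-heavy) and Pearson's $r$;
(3) divide each type's correlation vectors by their maxima; (4) keep
genes whose normalized $\tau$ and $r$ both strictly exceed their
thresholds, except that a gene attaining the maximum (normalized value
exactly 1 — in particular the lead gene itself) always passes. Genes
claimed by more than two types are dropped entirely, and an all-zero
dummy column is appended. Thresholds may be global or per-type.

## The synthetic-data generator

`sim_spot_data()` draws ground truth from the model's own prior and then
samples counts from the likelihood, emulating the reference simulation
conditions: 800 spots, 7 types (one dummy), markers split
15/31/35/23/17/33/0 across types, $\lambda_0 = 0.2$,
$(a,b,a_0,b_0) = (10,1,0.1,1)$, $p_g \sim \mathrm{Unif}(0,1)$, mean 15
cells per spot (zero-truncated Poisson; only the mean is specified by the
study conditions, the Poisson shape is this package's choice). Note the
printed per-type split sums to 154 genes; we keep the split itself as the
authoritative default. The `dense` preset uses $\alpha = 2t_N$ (about 4–5
distinct types per spot) and `sparse` $\alpha = 0.45\,t_N$ (about two).
Marker over-expression truth is drawn log-normal(meanlog 1, sdlog 1) — a
stand-in for resampled cell-type averages from an external single-cell
reference, which would require a download; the sampler is configurable
(`lambda_sampler`). The simulated dummy indicator is held at zero: the
dummy represents types absent from the signature, and the synthetic
ground truth contains none, matching the shrinkage assumption used at
inference. Overlap regimes re-mark 9 genes of type 2 as markers of type
3 and 10 of type 3 for type 4 (`slight`), plus all 17 of type 5 for type
4 (`high`), keeping the total gene count fixed.

Observed cell counts can be corrupted with Gaussian noise $N(2,3)$
("moderate") or $N(5,5)$ ("high"), randomly added or subtracted, rounded
and floored at 1, or withheld entirely ("unknown").

What the generator does *not* emulate: spatial autocorrelation of
compositions (spots are exchangeable), library-size variation beyond cell
count, zero-inflation, or segmentation artifacts in the counts. Passing
recovery tests on these data therefore demonstrates correctness of the
inference machinery under the model's own assumptions, not robustness to
real-tissue misspecification.

## Evaluation metrics

* `proportion_error()` — mean over spots and types of
  $|h - \hat h|$, bounded by $2/t_N$ (0.29 at $t_N = 7$);
* `dominant_type_accuracy()` — fraction of spots whose estimated argmax
  type matches the truth (ties broken to the lowest index, with a
  warning);
* `morans_i()` — spatial autocorrelation of a per-spot quantity on a
  symmetric k-nearest-neighbour graph (k = 6, matching hexagonal spot
  packing). The raw weights enter the formula as given — unlike
  `ape::Moran.I`, which row-normalizes them (the two agree on
  row-stochastic weights, which the test suite exploits as a
  cross-check);
* `cooccurrence()` — Pearson correlations of type proportions across
  spots with product-moment p-values, flagged at the 0.05 level (no
  multiplicity correction — matching how such matrices are usually
  displayed);
* `gelman_rubin()` — potential scale reduction from two or more chains.

## Scaled-down benchmark sizes

The reference study conditions (800 spots, 15 replicates per condition,
$\ge 10^5$ iterations, multiple chains) are a cluster-scale computation.
The package's standard benchmark (`deconv_benchmark()`, used by the test
suite and `scripts/acceptance.R`) runs each condition at 160 spots, 3
replicates and 4,000 iterations (burn-in 2,500, thinning 5, one chain,
adaptation every 250 burn-in iterations with $\epsilon = 0.3$ — the
faster adaptation compensating the shorter run, as the method's own
guidance suggests for small runs). These sizes are the package's chosen
desk-scale operating point; the error ceilings quoted for the full-size
study are still used as the reference values. Because each replicate is
~5x smaller and runs ~30x fewer iterations than the original, individual
replicates are noisier; medians over replicates are compared against the
full-size medians one-sidedly (smaller is better).

Two conditions of the wider original grid (sparse mixing with noisy or
unknown counts) are available through `deconv_benchmark(conditions =
...)` but are not part of the default benchmark, which covers the six
conditions with quoted reference values.

## Numerical choices

* All probability computations in log space; `lgamma` throughout. The
  compiled NB log-pmf uses $\log\Gamma(k+r) - \log\Gamma(r) =
  \log\prod_{j<k}(r+j)$ for counts below 25 (one `log` instead of two
  `lgamma` calls);
* truncated-normal proposals are drawn by rejection (the truncation point
  is at most half the mass away);
* a proposal with $-\infty$ log-target (e.g. $p_g \ge 1$) is a rejection,
  never an error; a non-finite log-likelihood aborts the run with the
  iteration index;
* ties in `dominant_type_accuracy()` go to the lowest type index with a
  warning; an all-zero abundance row is an error (`proportions_from_
  abundance` requires strictly positive entries);
* `Matrix::readMM` / `writeMM` handle MatrixMarket IO; dense readers
  sniff the separator from the file extension.

## Known limitations

* Presence/absence ($Z$) and abundance ($\theta$) mix by random-walk
  moves only; types whose markers overlap heavily can exchange mass
  slowly in sparse tissue.
* The scale ridge described above makes $\lambda_0$/$\Lambda$/$N_s$
  point estimates meaningful only with anchored counts.
* The dense likelihood loop is quadratic in (genes x spots); thousands of
  spots with hundreds of markers are feasible, full transcriptomes are
  not intended.
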