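---
title: "Inferring recombination landscapes from a single genome pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring recombination landscapes from a single genome pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhomap)
```

## The model

Along a chromosome, the genealogy of two sampled sequences changes wherever
an ancestral recombination event altered their time to the most recent
common ancestor (TMRCA). The sequentially Markovian coalescent with
back-coalescence (SMC') treats this spatial process as Markov: at each site
a tree of scaled height $s$ (time in units of $2N_e$ generations, so the
prior TMRCA is Exp(1) under a constant population) recombines with
probability $1 - e^{-\rho s}$, the breakpoint falls uniformly on the two
branches, and the floating lineage re-coalesces at the demography's rate
$\lambda(\tau)$ — possibly back onto its own branch, which restores the old
TMRCA. The per-site density of observable genealogy changes is therefore
proportional to the local population recombination rate $\rho = 4 N_e r$.

rhomap discretises scaled time into $t$ intervals of equal prior
coalescent mass and models the local $\rho$ as $\rho_0 r_l$, where $r_l$
are the $k$ equal-probability category means of a Gamma distribution with
shape = rate = $\alpha$ (mean one). The category index evolves as its own
Markov chain with per-site switch probability $\delta$ shared uniformly
among the $k-1$ other categories. The combined process is a
Markov-modulated hidden Markov model on $n = t \times k$ states
{TMRCA interval, rate category}: block $(l, m)$ of its transition matrix is
$P_{lm} \, Q_{\mathrm{SMC'}}(\rho_0 r_l)$, the genealogy step being taken
under the source (row) category's rate. A switchable option
(`rate_from = "destination"`) uses the destination category instead; the
two differ only at order $\delta$.

Observations are per-site codes: homozygous, heterozygous, or missing.
Under the infinite-sites model a site with TMRCA $\tau$ is heterozygous
with probability $1 - e^{-\theta \tau}$ ($\theta = 4 N_e \mu$); missing
sites emit with probability one in every state, so they are uninformative
but preserve the chain.

## Estimation

`rhomap_fit()` maximises the forward likelihood with Powell's
direction-set method over $\log \rho_0$, $\mathrm{logit}\,\delta$,
$\log \alpha$ and, optionally, five spline knots (below). $\theta$ is fixed
beforehand from the global heterozygosity $\hat h$ among non-missing sites
as $\hat\theta = -\log(1-\hat h)$; only products $\theta s$ and $\rho s$
are identifiable, so an error in this plug-in rescales time but leaves the
decoded landscape essentially unchanged. The homogeneous model ($k = 1$,
the PSMC'-like null) is fitted first and warm-starts the heterogeneous fit;
`select_model()` compares the two by AIC. For low-quality samples,
`decode_with_fixed_prior()` implements the two-step protocol: fit only the
demography on the sample itself ($k = 1$), then decode with externally
supplied $(\rho_0, \alpha, \delta)$ from high-quality samples.

Posterior decoding (forward–backward) yields per-site joint posteriors
over the $n$ states; `posterior_mean_rho()` reduces them to
$\bar\rho_i = \rho_0 \sum_l r_l \sum_j P_i(x_l, y_j)$, a convex combination
of the category rates. `time_restricted_rho()` instead conditions the
category posterior on the per-site MAP TMRCA interval and lets downstream
binning keep only sites whose MAP interval is at most a chosen index,
focusing the map on recent recombination. `max_interval = t` keeps every
site; sites whose MAP interval carries essentially no posterior mass fall
back to the unrestricted marginal and are flagged.

### Demography

Coalescence rates are parameterised by a natural cubic spline through five
(log time, log rate) knots — two endpoints (0.02 and 8 scaled time units)
and three internal knots (0.1, 0.5, 2.0), spanning the bulk of the
coalescent prior — frozen into a piecewise-constant rate function and
projected hazard-preservingly onto the TMRCA intervals, so interval prior
masses stay exactly equal. The number of demographic parameters is five
regardless of $t$. The discretisation is rebuilt from the current
demography at every likelihood evaluation, preserving the equal-mass
property during optimisation.

## Numerical choices

* **Transition kernel by quadrature.** For each source interval, the tree
  height $s$ is integrated at conditional prior quantile nodes (5 by
  default) and the breakpoint by Gauss–Legendre nodes per hazard piece,
  with all re-coalescence integrals closed-form for piecewise-constant
  $\lambda$. Because $s$ is averaged against the prior, the discretised
  prior is numerically an exact stationary distribution of the kernel
  (residuals around 1e-7 under the constant demography at default
  nodes). A multi-million-draw
  single-step Monte-Carlo simulation of the same experiment is the
  correctness oracle in the test suite.
* **Representative times.** Emissions use the conditional prior mean TMRCA
  per interval; the final (infinite) interval's mean is capped at five
  times the penultimate boundary to keep emissions finite under extreme
  demographies.
* **Run-length compression.** The forward recursion advances over maximal
  runs of identical symbols using cached binary powers of the per-symbol
  update matrices (each power stored normalised with a log scale factor).
  This is exact to floating point and gives two-orders-of-magnitude
  speed-ups at human-like diversity ($\theta \approx 0.003$); posterior
  decoding streams per-site quantities with checkpointing, in
  O(n × chunk) memory.
* **Optimisation.** Powell with Brent line searches
  (tolerance 0.05 on transformed scales), relative log-likelihood
  tolerance 1e-4, parameter tolerance 1e-3, direction-set reset every
  $n_{par}$ iterations to avoid degenerate direction sets, and box
  constraints $\rho_0 \in [10^{-6}, 0.1]$, $\delta \in [10^{-8}, 0.5]$,
  $\alpha \in [0.05, 20]$ for numerical safety. Fits are deterministic
  given data and settings.
* **Ties and edges.** MAP intervals break ties toward the more recent
  interval; Spearman correlations use average ranks; UPGMA merges are
  deterministic through `hclust`; a trailing partial window is kept when
  at least half the window width remains.

## The synthetic-data generators

`sim_rho_landscape()` / `sim_theta_landscape()` draw piecewise-constant
multiplicative landscapes: Gamma($\alpha$, $\alpha$) segment scales with
geometric segment lengths (mean $g$) for recombination; uniform scales on
[0.1, 10] (mean 5.05) with mean length $f$ for mutation. The benchmark
designs use $\alpha \in \{0.5, 5\}$, $g \in \{100\,\mathrm{kb},
1\,\mathrm{Mb}\}$, $\theta = 0.003$, $\rho_0 = 0.0012$.

`sim_smc_sequence()` simulates the pair sequentially with a *continuous*
TMRCA (only the inference discretises time, so the generative process is
not the fitted model's twin), under any piecewise demography.
`sim_hmm_path()` is the exact generative twin of a fitted kernel, used for
parameter-recovery tests. Structured scenarios — introgression pulses and
multi-population cohorts sharing a landscape — are delegated to msprime
through a bundled Python driver (`sim_structured_pairs()`), since pairwise
sequential simulation with population structure is a different machine.

Event times follow the benchmark's generation counts: with time in $2N_e$
generations, the 20-fold expansion sits at 0.02, the 20-fold bottleneck at
1.0, and the introgression design splits source and target at 4.0 with a
10% pulse at 0.25 or 0.5. (The source texts quote these in
$4N_e$-generation simulator units — 0.01, 0.5, 2.0, 0.125/0.25 — their
stated generation equivalents fix the conversion.)

What these simulations do *not* emulate: sequencing error, reference bias,
gene conversion, selection, trapped non-ancestral material, and realistic
missing-data structure. Passing benchmarks therefore demonstrates
correctness of the method under its own assumptions, not field accuracy on
real data.

## Study sizes and what the benchmarks show

The package's reproduction study runs at desk scale, chosen once from
signal-density arithmetic: 5 Mb sequences and 3 replicates per landscape
scenario with a 10 × 5 discretisation (the full-scale study uses 30 Mb,
10 replicates, 200 hidden states); 6 Mb for the population-expansion arm,
whose ten-fold shorter trees dilute SNP density to ~2 × 10⁻⁴ per site; and
1.5–2 Mb where trees are long and SNPs abundant. Median $R^2$ between true
and inferred maps in 50 kb windows is the headline quantity; medians pool
replicates within each study arm.

Two caveats discovered while building the package are worth recording.
First, at 2 Mb with $\delta = 10^{-5}$ a sequence holds only ~20 rate
dwells, so the likelihood identifies the *realised* landscape mean, which
scatters 30–50% around $\rho_0$; recovery of the prior parameters to
within 20% is only meaningful from ~10 Mb upward, and the test suite
checks it there. Second, in the expansion scenario the genealogy-change
density is $\rho_0 E[s] \approx 10^{-4}$ per site — about three observable
transitions per 50 kb window — which caps the achievable window-level
$R^2$ near 0.1–0.2 regardless of fitting quality (a decode with the true
generative parameters does no better); the pooled demographic-history
median reflects that ceiling together with the near-0.8 bottleneck arm.

## Known limitations

Single pair only (no multi-pair or phased extensions); no gene-conversion
tracts; $N_e$ and $r$ are not separable from $\rho = 4 N_e r$; Viterbi
paths are not produced (posterior decoding only); the spline demography is
a smoothing device, not a formal population-size estimator.
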