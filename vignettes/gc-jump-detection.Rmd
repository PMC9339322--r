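---
title: "Detecting evolutionary jumps in genomic GC content: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting evolutionary jumps in genomic GC content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the models

Bacterial genomic GC content spans roughly 13–75% and is usually strongly
conserved within clades, yet some lineages — endosymbionts most famously —
have shifted it dramatically over short phylogenetic distances. This
package asks, for a rooted phylogeny with branch lengths in substitutions
per site and one GC percentage per tip, whether the trait evolved
gradually or through episodic jumps, and if the latter, *where* the jumps
happened, how big they were, and whether their direction tracks ecological
lifestyle changes.

Three nested models of a continuous trait $x$ are compared:

* **Brownian motion (BM).** Increments along a branch of length $t$ are
  $\mathcal N(0, \sigma_0^2 t)$. Tips are jointly multivariate normal with
  mean $x_0$ (the root state) and covariance $\sigma_0^2 C$, where
  $C_{jk}$ is the shared root-to-MRCA path length.
* **Single-optimum Ornstein–Uhlenbeck (OU).** BM plus a restoring force of
  strength $\alpha_{OU}$ toward an optimum $\theta$. We constrain the root
  to the optimum ($x_0 = \theta$), the common default for a single-optimum
  model, and use the fixed-root (non-stationary) covariance because the
  trees are non-ultrametric:
  $\mathrm{Cov}(i,j) = \frac{\sigma^2}{2\alpha_{OU}}
  e^{-\alpha_{OU}(d_i + d_j - 2 t_a)} (1 - e^{-2\alpha_{OU} t_a})$
  with $d_i$ the tip depths and $t_a$ the MRCA depth. As
  $\alpha_{OU} \to 0$ this converges continuously to BM; whether a
  stationary- or fixed-root form is used does not affect that collapse.
* **Lévy jumps.** BM plus jumps arriving as a Poisson process with rate
  $\lambda$ per unit branch length; each jump's magnitude is drawn from
  $\mathcal N(0, \alpha\,\sigma_0^2)$, i.e. the per-jump variance is a
  multiple $\alpha$ of the Brownian rate. Conditional on the per-branch
  jump counts $n_i$, the model is exactly BM with effective branch lengths
  $t_i + \alpha n_i$ — the observation all the machinery in this package
  rests on. Note that $\alpha$ (relative jump size) and $\alpha_{OU}$
  (OU constraint) are unrelated parameters that happen to share a letter
  in the field's notation; they are kept in separate parameter objects.

The marginal Lévy likelihood sums the conditional Gaussian likelihood over
all jump configurations weighted by their Poisson prior. A likelihood-ratio
test of Lévy against BM uses $\chi^2_2$ (two added parameters, $\lambda$
and $\alpha$; the degrees of freedom are configurable since jump-model
regularity is imperfect), with reported p-values floored at $10^{-16}$.

A cheap first diagnostic sits alongside the fits: the excess kurtosis of
variance-scaled phylogenetically independent contrasts. Under BM the
contrasts are i.i.d. normal (excess kurtosis 0); jumps fatten the tails.
Kurtosis is the plain central-moment ratio $m_4/m_2^2 - 3$ with no
small-sample correction.

# Estimation machinery

**Pruning core.** All Gaussian likelihoods are computed in $O(N)$ by
Felsenstein's pruning algorithm (implemented in C++), which also yields
the GLS root estimate, its variance, the quadratic form and the
log-determinant, so the closed-form BM MLEs
($\hat x_0$ = GLS mean, $\hat\sigma^2$ = ML quadratic form over $N$; ML
rather than REML, so rates are comparable with standard package defaults)
come from a single pass. The OU fit profiles $\alpha_{OU}$ on a log grid
over $[10^{-8}, 10/\text{tree height}]$ with $\theta, \sigma^2$ solved by
GLS at each grid point, iteratively refined, and always includes the exact
BM boundary as a candidate; an interior optimum must beat the boundary by
more than $10^{-7}$ log units so numerically flat profiles collapse to
$\alpha_{OU}=0$.

**EM + MCMC for the Lévy model.** With $\alpha$ fixed, the latent jump
counts are integrated by Monte-Carlo EM. The E-step runs a Metropolis
sampler over configurations: single-branch $\pm 1$ proposals with
reflection at zero (Hastings-corrected), plus jump-relocation moves that
shift one jump to an adjacent branch — without relocation a jump that the
data place ambiguously between neighbouring branches mixes very slowly.
Each likelihood ratio only recomputes the pruning path from the modified
branch to the root. The M-step is closed-form:
$\lambda \leftarrow$ mean sampled jump total / total tree length, and
$(\sigma_0^2, x_0)$ maximize the sample-averaged complete-data Gaussian
log-likelihood. Because the per-iteration updates carry sampling noise, a
deterministic-EM stopping rule never fires; convergence is instead judged
on running means over an 8-iteration window (relative drift $< 5\times
10^{-3}$ three times in a row) and the reported estimate is the
last-window average — standard Monte-Carlo-EM smoothing. $\alpha$ itself
cannot be updated inside EM, so it is profiled over the grid
$\{0.1, 0.25, 0.5, 1, 2, 4\}$ (per-jump variance from 10× smaller to 4×
larger than the Brownian rate) and the grid value with the largest
estimated marginal log-likelihood wins; a boundary maximum triggers a
warning.

**Marginal likelihood.** Three estimators, in increasing order of
robustness: exact truncated enumeration (per-branch truncation keeps
$1 - 10^{-6}$ Poisson mass; guarded at $10^6$ configurations) — the
correctness anchor on small trees; prior Monte Carlo (average the Gaussian
density over Poisson-prior draws) — simple and unbiased but useless beyond
tens of branches because the posterior occupies an exponentially small
corner of the prior; and annealed importance sampling — each particle is
pulled from the prior to the posterior through a geometric ladder of
likelihood-tempered distributions ($\beta_k = (k/K)^2$, finer near the
prior) with Metropolis sweeps at each rung. A mean-field importance
sampler was tried first and found biased low by tens of log units at 300
tips; AIS matches the exact enumerator on small trees and is what the fits
report whenever enumeration is infeasible. Fit comparisons therefore carry
Monte-Carlo standard errors, and the pipeline's likelihood-ratio test
clamps its statistic at zero with a tolerance tied to those errors.

**Branch posteriors.** With parameters fixed at their estimates (the
empirical-Bayes step), the posterior probability that branch $i$ carries
$\ge 1$ jump is the fraction of retained MCMC samples with $n_i \ge 1$.
Two independent chains are run; their maximum per-branch disagreement is
reported, with a warning (never silence) above 0.05. Defaults: 4000 sweeps,
400 burn-in. A handful of genuinely bimodal placements can keep the
diagnostic near 0.06 even at long runs; the reported posterior averages the
chains.

# Threshold calibration, magnitudes, ecology

Calibration follows the simulate-with-known-truth design: five datasets
are simulated on the same tree under the fitted parameters, posteriors are
re-inferred blind (parameters fixed at the values used to simulate,
matching how thresholds were calibrated on real-data fits; refitting per
simulation is available behind a flag), and branches are classified at
each threshold in a 0.05-step sweep that always includes 0.75, 0.90 and
0.95. Precision is $100\,TP/(TP+FP)$ and recall $100\,TP /$ (branches
carrying $\ge 1$ simulated jump) — multiple jumps on one branch count as
one detectable event, since only cumulative change per branch is
observable; numerators and denominators are pooled across simulations
before dividing. The chosen threshold maximizes recall subject to pooled
precision $\ge 90\%$ (ties toward the lower threshold); if nothing
qualifies, the highest-precision threshold is returned flagged
unattainable. Precision at a threshold where nothing was inferred is
undefined and excluded, never 0 or 100. Recall stratified by true jump
magnitude is reported in 5-GC% bins; because the upper bins hold only
tens of branches, monotonicity is *tested* as a positive rank trend
between magnitude and detection rather than bin-by-bin.

A jump call is any branch with pp strictly above the threshold, indexed in
preorder. Its magnitude is the median GC of tips descending from the
called branch minus the median GC of tips descending from its sister
branch (the parent must be binary; polytomies are rejected explicitly
everywhere a sister or contrast is needed, because silent resolution would
change the estimates). Tips lying under any *other* called branch nested
inside either side are excluded first, on both the affected and the sister
side; a call whose sister is entirely excluded is reported "magnitude
unavailable" rather than dropped. On noise-free planted shifts this
estimator is exact, which the tests assert to $10^{-9}$.

Whether calls sit unusually deep or shallow is tested against jumps placed
at random with probability proportional to branch length: the observed
branch-midpoint depths are compared to the pooled null by
Kolmogorov–Smirnov distance, with a Monte-Carlo p-value from the
per-draw distances (midpoint depth and the KS statistic are choices the
data do not dictate; both are isolated in one function).

Ecological association uses a closed vocabulary (host_dependent /
host_associated / not_host_dependent / unknown; anaerobic < facultative <
aerobic ≤ obligately_aerobic, assigned per clade by majority with ties to
unknown). host_gain means the affected clade is host-associated while the
sister is free-living; unknowns propagate, never guessed. Direction ×
switch tables are tested with a two-sided Fisher's exact test implemented
from log-factorials (minimum-likelihood two-sided rule with the
conventional $1+10^{-7}$ tie guard; sample odds ratio with a
Haldane–Anscombe 0.5 correction when a cell is zero). Display percentages
round half-up, so 15/19 prints as 79% and 4/12 as 33%.

# The synthetic-data generator

`generate_dataset()` emulates a de-replicated order-level clade: a Yule
tree (default 200–400 tips; pure birth with a final exponential hold so
mean tip depth at unit rate is $\sum_{k=2}^{n} 1/k$), multiplicative
lognormal branch jitter (sdlog 0.3) to mimic non-ultrametric
substitutions-per-site trees, Lévy-jump trait evolution, optional
reflecting boundaries on GC (default 25–75 when used — reflection is the
simplest mechanism that reproduces the observed tendency of low-GC clades
to jump up and high-GC clades to jump down; the real constraint mechanism
is unknown), and per-jump ecological annotations whose direction–switch
association is controlled by `ecology_effect` (0 = independence;
annotation direction is the realised branch change, after reflection).
Default rates for the worked analyses, chosen once to sit inside the
fitted ranges reported for real order-level clades: $\lambda = 4$ jumps
per unit branch length (reported span ~2.5–6), $\alpha = 4$, Brownian rate
30 GC%² per unit branch length, ancestral GC 50%.

What the generator does *not* emulate: taxonomic sampling bias beyond the
de-replication step, among-clade rate heterogeneity, trait-dependent
diversification, measurement error in assembly GC, and any non-Gaussian
jump kernel. Passing tests therefore show the machinery is correct and
well calibrated under its own model, not that real GC evolution obeys it.

# Numerical and design notes

* De-replication collapses every maximal clade whose height (max
  node-to-tip path) is below the threshold (default use case: 0.01
  substitutions/site) to its lexicographically smallest tip label —
  deterministic without random state; height-vs-mean and tip choice are
  the two unstated details of the original procedure, recorded here as
  the package's convention.
* Zero-length terminal branches are allowed except where they make a
  contrast denominator zero, which is an error.
* The annotated-Newick dialect puts `[&key=value]` after the label and
  before the colon; the reader extracts comments by token substitution and
  delegates topology to `ape`, and the syntax pre-scan reports the byte
  offset of the first unbalanced parenthesis or missing semicolon.
* All randomness flows from one integer seed; sub-streams are derived
  arithmetically per (stage, replicate) and kept inside 32-bit range.
  Same seed, same result, bit for bit.
* Problem sizes used by the shipped analyses and checks: 300-tip trees for
  parameter recovery (20 replicates, EM at 50 iterations × 100 sweeps),
  200-tip trees for calibration (5 simulations), 80-tip trees for the
  no-jump null (200 cohorts), 400-tip cohorts for the
  ecology-independence null. The last choice is deliberate: Fisher's
  exact p-values are discrete and conservative, and below roughly 100
  jumps per cohort a uniformity diagnostic measures that discreteness
  rather than the generator, so the null check runs at the upper end of
  the realistic clade-size range.

# Known limitations

* Under a no-jump truth the Lévy-vs-BM likelihood-ratio statistic has its
  null on the boundary of the parameter space: roughly half to
  three-quarters of null datasets give a statistic of exactly zero, so
  p-values referred to $\chi^2_2$ are conservative and *not* uniform.
  The test is still valid for rejecting BM (conservative), but its null
  p-distribution should not be expected to pass a uniformity check; the
  same boundary effect applies to OU-vs-BM.
* The EM's $\lambda$ estimate is moderately biased low (and $\sigma_0^2$
  correspondingly high) at desk-scale MCMC settings; the totals
  $\sigma_0^2(1 + \lambda\alpha)$ are recovered well. Longer E-steps
  shrink the split bias.
* Posterior probabilities for jumps that the data place ambiguously
  between adjacent branches are genuinely split; calibration (the
  fraction of mid-pp branches truly carrying jumps) is checked coarsely,
  not per-branch.
* Magnitude estimates are sister-median approximations, not model-based
  jump-size estimates; the underlying model deliberately does not expose
  per-branch jump sizes.
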