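---
title: "Time-varying causal networks from plankton time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying causal networks from plankton time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(planknet)
```

## The problem

Lake plankton communities are nonlinear, seasonally forced dynamical
systems. Correlation-based statistics routinely miss, or invent,
dependencies between their guilds, because nonlinear state dependence
decouples correlation from causation. `planknet` implements an
equation-free route: it reconstructs each guild's attractor from its own
monthly time series (time-delay embedding), asks how well that attractor
estimates the states of a putative driver (convergent cross-mapping,
CCM), tracks that skill through time in moving windows, and discounts
the part of the skill that mere shared seasonality can explain (seasonal
surrogates). The surviving, seasonally corrected skill per window is
read as a time-varying interaction strength, and the resulting link
series are condensed into network properties — connectance, mean
interaction strength, top-down minus bottom-up control, interaction-type
structure — which are in turn modelled over temperature and phosphate
gradients with multivariate S-maps to explore warming and
re-oligotrophication scenarios.

## The empirical dynamic modelling kernel

**Embedding.** A series $x_t$ (z-scored; sample sd, $n-1$) is embedded as
$(x_t, x_{t-\tau}, \dots, x_{t-(E-1)\tau})$ with $\tau = 1$ month
throughout. The dimension $E$ is chosen per variable by leave-one-out
simplex projection over $E = 2,\dots,15$ at horizon $t_p = +1$,
maximizing the forecast skill $\rho$ (Pearson correlation of predictions
and observations); ties go to the smallest $E$.

**Simplex projection.** Each prediction uses the $E+1$ nearest library
points (Euclidean distance on the z-scored coordinates), weighted
$w_i = \exp(-d_i/d_1)$ with $d_1$ the nearest distance. Numerical
choices: weights below $10^{-6}$ of the maximum are clamped to that
floor (avoids 0/0); if $d_1 = 0$, all zero-distance neighbours share
equal weight; the target itself, any row within the exclusion radius,
and any row with a missing coordinate or target are never neighbours.
These conventions are asserted against a brute-force all-pairs oracle in
the test suite.

**Cross-mapping.** To test driver → affected, the *affected* variable is
embedded and its simplex neighbours estimate the *driver*'s values; the
skill $\rho$ of that estimate measures how much of the driver is
imprinted on the affected dynamics. Horizon conventions follow the
stage: $t_p = +1$ for embedding-dimension selection, $t_p = 0$ for the
convergence stage, $t_p = -1$ for the final full-library cross-map. All
three are explicit configuration fields.

**S-map.** A locally weighted linear regression is solved at each query
point with weights $\exp(-\theta d_i / \bar d)$ and an SVD
pseudo-inverse, so rank-deficient designs (e.g. constant morphometry
columns in single-lake blocks) are handled; $\theta = 0$ reduces exactly
to global least squares, which the tests verify to $10^{-8}$ against
`lm()`.

## From pairwise skill to a time-varying network

For every candidate directed link of the guild template:

1. **Convergence screen.** Cross-map skill is computed on 100 contiguous
   random library segments at 20% and 50% of the usable points; the link
   passes if a paired one-sided t-test finds the 50% skills larger at
   the 5% level. "Consecutive random subsets" is read as contiguous
   segments with uniformly random starts — "consecutive" describes the
   samples within a subset.
2. **Local skill.** One full-library cross-map at $t_p = -1$; Pearson
   skill within 60-month windows sliding one month at a time, stamped at
   the window centre (a window starting at month $s$ is stamped
   $s + 29$, the integer floor of its midpoint; windows with fewer than
   3 complete pairs are flagged skipped).
3. **Seasonal surrogates.** 100 null driver series preserving the
   monthly climatology exactly while permuting within-calendar-month
   anomalies across years. The cited literature offers several seasonal
   nulls; this scheme was chosen as the least-assumption one (it
   conserves the within-month value sets, so the seasonal cycle is
   reproduced exactly). Because the null concerns the driver's seasonal
   signal, each surrogate replaces the driver series only — the affected
   manifold and its neighbour weights are reused unchanged, which also
   makes the ensemble cheap.
4. **Significance and strength.** A window is significant when the
   original skill strictly beats at least 95% of the surrogate ensemble
   (ties count against significance — with $n$ surrogates the threshold
   is $\lceil 0.95\,n \rceil$). Where significant, strength is
   `local_rho - mean(surrogate rho)`, floored at 0; elsewhere 0.

Non-convergent pairs carry an all-zero strength series flagged
non-convergent. Per-pair random draws are seeded from the master seed
plus a stable hash of the ordered pair label, so adding or removing
pairs never perturbs existing results. No multiple-testing correction is
applied across pairs; the surrogate test is the only significance
filter, and the per-window false-positive rate on independent
seasonally forced pairs is measured (about 5%) in the acceptance suite.

## Network properties

Connectance is $C = 100\,L/L_\mathrm{possible}$ per window. The default
denominator is the count of template links that passed the convergence
screen (the network-construction convention); `all_ordered_pairs`
($N(N-1)$) and `template_all` (every candidate link) are available, and
the choice is recorded in the result's attributes. Trophic control
restricts to trophic and hybrid links, normalizes top-down and bottom-up
counts by their own possible-link counts, and reports the differences
(positive = top-down control); a class with no significant links
contributes connectance 0 and strength `NA`, so the strength difference
is `NA` for that window. Interaction-type decomposition uses the same
rule per type, and per-window type counts recompose the total link count
exactly (a test asserts the identity). A link collapses to a scalar as
mean strength over significant windows × prevalence (fraction of windows
significant). Trends are Spearman rank correlations against time within
configurable period cut-offs (default: the series midpoint separates the
re-oligotrophication-dominated early period from the warming-dominated
late one); type comparisons are rank-sum tests on per-lake means, exact
for groups of at most 10 without ties.

## Scenario exploration

A network-property series is modelled as a function of 60-month-smoothed
temperature and phosphate plus lake depth and volume. $\theta$ is chosen
on the grid $(0, 10^{-4}, \dots, 8)$ by cross-validated skill with a
12-month exclusion radius (the moving windows induce strong serial
correlation; excluding a year around each query prevents leakage), ties
to the smaller $\theta$. The scenario surface averages 100 S-map models,
each fit on a random half of the rows (uniform draws without
replacement by default; contiguous blocks behind a flag), evaluated at
every cell of a temperature × phosphate grid with depth and volume held
at the lake's values; the cell standard deviation across models is the
uncertainty estimate. The key engineering choice here is that the S-map
is solved *at the query vector itself* — distances run from the grid
point to the library rows — rather than only at library rows, which is
what grid prediction requires; grid queries carry no time stamp, so no
temporal exclusion applies to them. Predictors are standardized with the
full block's statistics, and grid queries are transformed with those
same statistics. A 95% observed-range mask separates interpolation from
extrapolation; on a known smooth surface the tests show grid error below
the observation noise inside the mask and a larger ensemble spread
outside it.

## The synthetic food web

No public generator accompanies monitoring data of this kind, so the
package ships its own ground-truthed stand-in: a discrete-time
multispecies Ricker map

$$N_{t+1,i} = N_{t,i}\exp\!\big(r_i s_i(t) + \textstyle\sum_j C_{ij} N_{t,j}
 + \beta_i^T z_T(t) + \beta_i^P z_P(t) + \varepsilon_{t,i}\big),$$

with a 12-month sinusoidal forcing $s_i(t)$, signed coupling matrix $C$
(diagonal = self-regulation), standardized driver anomalies, Gaussian
process noise and lognormal multiplicative observation noise (plankton
counts are positive and right-skewed). The Ricker family is the
standard nonlinear benchmark in this literature: it is chaotic at the
chosen growth rates (2.5–3.1), seasonally entrained, and admits
arbitrary signed coupling. Defaults emulate the target monitoring
setting: 8 guilds in three trophic levels observed monthly for 40
years; temperature as an annual sinusoid (mean 10 °C, amplitude 4 °C)
with a +0.3 °C/decade ramp and AR(1) anomalies; phosphate as a seasonal
cycle around an exponentially declining baseline (−40%/decade from
60 µg/L) with lognormal AR(1) anomalies, optionally modulated by the
temperature anomaly (warm years mix less, default −0.3 per °C). Biotic
coupling defaults to +0.1 (prey on predator) and −0.25 (predator on
prey), i.e. top-down effects stronger than bottom-up, and producers are
sensitive to phosphate (+0.2) with two guilds temperature-sensitive. The
noise defaults (process 0.02, observation 0.05 on the log scale) are
calibration choices — the monitoring literature does not state the real
data's noise level — picked once as "low noise" so that recoverability
failures indicate method problems rather than hopeless data.

What the generator does *not* emulate: lake physics (stratification,
mixing), size structure, observation effort changes, taxonomic drift.
Passing tests therefore demonstrate that the pipeline recovers known
structure under nonlinear, seasonal, trending conditions — not that any
specific lake's biology is reproduced.

## Validation experiments and problem sizes

The test suite runs desk-scale versions of every experiment: exact
oracle equivalence of the kernels (50 random series, 20 random
regression blocks); near-perfect forecasting of the noise-free logistic
map; direction recovery on a two-guild unidirectional web over 20 seeds
(480 months); false-positive control on 100 independent seasonally
forced pairs (50 surrogates); topology recovery on the default 8-guild
web, where ranking candidate links by prevalence-weighted strength
separates true from false edges (rank-AUC ≥ 0.8); exact metric
identities on hand-built link series; scenario-surface recovery on a
30 × 30 grid; and byte-identical reruns of a reduced pipeline (6
guilds, 360 months, 50 surrogates, 25 × 25 grids). These sizes are the
package's chosen validation conditions; larger runs only tighten the
same checks.

## Known limitations

- **The convergence screen is anticonservative under seasonality.**
  For two independent but seasonally forced series, cross-map skill
  *genuinely* increases with library size (the seasonal map is estimated
  better from more years), and a paired t-test over 100 subsets has the
  power to flag that tiny systematic increase; on the synthetic
  conditions most independent seasonal pairs pass the screen. Even on
  independent white noise the test is liberal (Monte-Carlo size near
  0.17 rather than the nominal 0.05), because the contiguous random
  subsets overlap heavily and the resulting dependence deflates the
  t-test's standard error. The surrogate stage is what restores
  specificity — it holds the per-window false-positive rate near the
  nominal 5% — so the convergence flag should be read as "skill grows
  with library", not as causality by itself.
- **Driver–driver feedback and synchrony.** When one stochastic driver
  forces another strongly, the forced variable approaches a function of
  its forcer and cross-map information flows both ways (generalized
  synchrony). The feedback test then reports genuine dependence in both
  directions; it cannot orient the arrow in that regime.
- **Partial guild sums.** A guild-month with some members missing uses
  the sum of observed members, which biases abundance low but preserves
  dynamics; only fully missing months become gaps.
- **No multiple-testing correction across links**, matching the
  network-construction convention; connectance is therefore a rate of
  surrogate-beating links, not a family-wise-controlled edge count.
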