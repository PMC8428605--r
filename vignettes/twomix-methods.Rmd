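---
title: "Methods: two-layer nonparametric empirical Bayes testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-layer nonparametric empirical Bayes testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twomix)
```

## The model

Each testing unit $i = 1, \dots, m$ contributes an estimated effect $x_i$
and a squared standard error $s_i^2$, with a single design-determined
degrees of freedom $\nu$ shared by all units (in a balanced two-group
comparison with $n$ samples per group, $\nu = 2n - 2$). The sampling model
is the classical normal-theory pair

$$x_i \mid \theta_i, \sigma_i^2 \sim N(\theta_i, \sigma_i^2),
\qquad
\frac{\nu\, s_i^2}{\sigma_i^2} \sim \chi^2_\nu,$$

independently across units given the latent $(\theta_i, \sigma_i^2)$. The
second line is what distinguishes this model from approaches that treat
$s_i$ as the exact standard error: with small $n$, $s_i^2$ is itself noisy,
and ignoring that noise distorts both the ranking of units and the
calibration of error-rate estimates.

Both latent quantities receive nonparametric priors supported on finite
grids:

- **Effects.** $\theta_i \sim g$ on a regular grid
  $a_{-K} < \dots < a_0 < \dots < a_K$, symmetric about the presumed mode
  $a_0$ (zero when a point null is retained). $g$ is constrained to be
  *unimodal about $a_0$*: $g_k \le g_{k+1}$ for $k < 0$ and
  $g_k \ge g_{k+1}$ for $k \ge 0$. The mass $g_0$ at the mode is the null
  proportion $\pi_0$.
- **Variances.** $\sigma_i^2 \sim h$ on a regular grid
  $0 < b_1 < \dots < b_L$, unconstrained apart from the simplex conditions.

Writing $p_i(k, l)$ for the joint density of $(x_i, s_i^2)$ given
$\theta_i = a_k$ and $\sigma_i^2 = b_l$, the marginal log-likelihood is

$$\ell(g, h) \;=\; \sum_{i=1}^m \log \sum_{k=-K}^{K} \sum_{l=1}^{L}
g_k\, h_l\, p_i(k, l),$$

maximized over the product of the two probability simplices subject to the
unimodality ordering on $g$. All density evaluations are done in log space
with per-unit log-sum-exp stabilization, so grids spanning many orders of
magnitude in density are handled without underflow.

Given the estimates $(\hat g, \hat h)$, each unit's posterior over the
effect grid is

$$P(\theta_i = a_k \mid x_i, s_i^2) \;\propto\;
\hat g_k \sum_l \hat h_l\, p_i(k, l),$$

from which two tail summaries are reported:

- $\mathrm{lfdr}_i = P(\theta_i = a_0 \mid \text{data})$, the local false
  discovery rate;
- $\mathrm{lfsr}_i = \min\{P(\theta_i \le a_0 \mid \text{data}),\,
  P(\theta_i \ge a_0 \mid \text{data})\}$, the local false sign rate.

Both cumulative masses include the atom at the mode, which yields the exact
invariants $\mathrm{lfdr}_i \le \mathrm{lfsr}_i \le (1 +
\mathrm{lfdr}_i)/2$; the upper bound is attained for symmetric posteriors
(e.g. $x_i = 0$ on a symmetric grid). Thresholding
$\{i : \mathrm{lfdr}_i \le \alpha\}$ gives a discovery list whose mean lfdr
estimates its false discovery rate; lfsr thresholding is uniformly more
conservative and its lists are always subsets of the lfdr lists at the same
level.

## The solver

The objective is concave in $g$ for fixed $h$ and in $h$ for fixed $g$, but
not jointly. The constraint set for $g$ (simplex plus ordering) is handled
by an exact reparameterization rather than by penalties or projections:
every pmf that is unimodal about $a_0$ is a convex combination of discrete
uniform distributions on grid intervals $[a_{lo}, a_{hi}]$ with
$lo \le 0 \le hi$ (a discrete layer-cake decomposition). Collecting those
$(K+1)^2$ uniforms as columns of a matrix $B$, the constrained problem in
$g$ becomes an *unconstrained-on-the-simplex* mixture problem in interval
weights $w$, with $g = Bw$ feasible by construction — the constraint
violation of a fit is exactly zero up to floating-point addition.

`twomix()` alternates two block maximizations until the objective is stable:

1. **Effect block.** With $h$ fixed, collapse the variance layer,
   $A_{ik} = \sum_l h_l\, p_i(k,l)$; the conditional objective
   $\sum_i \log (ABw)_i$ is an ordinary (concave) mixture likelihood in $w$.
2. **Variance block.** With $g = Bw$ fixed, collapse the effect layer,
   $H_{il} = \sum_k g_k\, p_i(k,l)$, and maximize $\sum_i \log (Hh)_i$
   over $h$.

Each block is solved by EM with squared-extrapolation acceleration: two EM
steps define a step pair $(r, v)$, an extrapolated iterate
$p - 2\alpha r + \alpha^2 v$ is tried with the step length clamped to a cap
that grows geometrically while extrapolation keeps succeeding and shrinks
on failure, and any non-improving trial falls back to the plain double EM
step. The objective therefore never decreases. A small mass floor
($10^{-15}$) is applied when projecting extrapolated iterates back onto the
simplex so that multiplicative updates can revive components driven to
zero by an aggressive extrapolation.

## Parameters and defaults

- **`K = 15`** (31 effect grid points). The effect grid spans
  $\pm\max_i |x_i - a_0|$, so every estimate lies inside the grid; 31
  points resolve the effect scale well below the sampling noise in the
  regimes the model is intended for, and the interval basis grows as
  $(K+1)^2$, keeping the weight vector modest (256 entries).
- **`L = 20`** variance grid points, regular on
  $[\min_i s_i^2, \max_i s_i^2]$. Grid-resolution diagnostics on simulated
  two-group data ($m = 1000$, $\nu = 18$) showed that the estimated null
  proportion still moves when $L$ is raised from 10 to 20 but is unchanged
  (to three decimals) from 20 to 30 or 40: a too-coarse variance grid
  under-resolves the $\chi^2$ sampling spread of $s_i^2$ and the model
  compensates by distorting $g$. The default sits at that saturation point.
- **`twomix_control(tol = 1e-7, max_outer = 100, inner_cycles = 50)`**.
  The outer loop stops when one full block cycle improves the objective by
  less than `tol * (|loglik| + 1)`. Profiling across scenarios showed that
  tightening `tol` from $10^{-7}$ to $10^{-10}$ changes fitted mixing
  weights by under $10^{-3}$ while multiplying runtime several-fold; since
  no reported quantity is meaningful at the fourth decimal of a mixing
  weight, the faster default is used and a tighter setting remains one
  argument away.
- **`subsample`** (default 1, i.e. off). For very large $m$, the mixing
  distributions can be estimated on a seeded random fraction of units —
  they are population quantities, so a large subsample estimates them
  nearly as well — while posteriors are still computed for every unit.
- **`mode = 0`**: the grid mode, i.e. the location of the point null.

## The simulation harness

`scenario()` defines generative configurations used to study operating
characteristics. Latent effects are drawn from
$\pi_0\, \delta_0 + (1 - \pi_0)\, g_\mathrm{alt}$ with named alternative
shapes expressed as normal mixtures (the parameterizations customary in the
adaptive-shrinkage simulation literature):

```{r}
str(twomix:::alt_shapes(), give.attr = FALSE)
```

`spiky` concentrates alternative mass near zero (the hardest separation
problem), `near_normal` is a mild two-component scale mixture, `flattop` is
nearly uniform on $[-1.5, 1.5]$, `big_variance` has wide effects that are
easy to separate, and `bimodal` violates the unimodality assumption on
purpose, to probe misspecification. Latent variances come from
`variance_model()`: a point mass, a two-point mixture, or an inverse gamma.
Observations are then per-unit Gaussian samples with $n$ per group, reduced
by `two_group_summary()` so that $\nu = 2n - 2$ — the harness exercises the
full pipeline rather than feeding the model its own summary statistics.
When a scenario leaves $\pi_0$ unspecified, each replicate draws
$\pi_0 \sim U(0.5, 1)$ and `run_operating_characteristics()` aggregates
empirical FDR and mean $\hat\pi_0$ within four $\pi_0$ strata. Estimation
error of $\hat g$ is scored by the 1-Wasserstein distance against the
generative effect distribution discretized on a fine grid.

All stochastic steps take explicit integer seeds; replicate seeds are
derived from one master seed, and every seeded helper restores the global
RNG state, so results are reproducible end to end.

## Numerical choices

- Component log-densities are computed once per fit as an
  $m \times (2K+1) \times L$ array; the $\chi^2$ factor does not depend on
  the effect index and is computed once per $(i, l)$.
- The per-unit maximum log entry is subtracted before exponentiation;
  a unit whose entire row underflows to $-\infty$ is detected and reported
  by id rather than propagating `NaN`.
- Block matrix-vector products use the collapsed forms above, so the hot
  loop multiplies $m \times (K+1)^2$ and $m \times L$ matrices instead of
  touching the full three-way array.
- Mesh validation: `mesh_fit()` enumerates *all* unimodal $g$ and all $h$
  on a mesh of the two simplices for tiny grids and returns the exact mesh
  optimum. It is deliberately restricted (at most 5 effect points, 2
  variance points) and serves as an independent oracle for the solver in
  the test suite.
- Output serialization uses 17 significant digits, so written results
  re-read bit-faithfully.

## Limitations

- **Weak identifiability of the null atom at small $n$.** When the grid
  spacing near zero is much smaller than the sampling noise
  ($a_1 - a_0 \ll \sigma_i$), a point mass at zero and a narrow spread over
  the adjacent grid points are nearly likelihood-equivalent, and the
  maximum-likelihood $\hat g$ may genuinely prefer the spread on datasets
  whose empirical dispersion slightly exceeds the best-fitting variance
  mixture. $\hat\pi_0 = \hat g_0$ is then biased low even though the
  *posterior* quantities remain conservative (the smeared mass sits on
  effectively null effects, and lfdr thresholding still yields empty or
  clean lists). This matters most for alternatives with substantial mass
  near zero at 10 or fewer samples per group; the bias shrinks rapidly with
  $n$.
- **$\hat\pi_0$ is not an upper-bound estimator.** Unlike procedures that
  deliberately over-estimate the null proportion, the MLE here can err in
  either direction; downstream FDR estimates inherit conservatism from the
  lfdr averaging instead.
- **Shared degrees of freedom.** The sampling model assumes one
  design-determined $\nu$ for all units; per-unit degrees of freedom
  (unbalanced missingness) are rejected at the data interface rather than
  approximated.
- **Non-convexity.** The joint objective may have multiple stationary
  points. The block-coordinate solver is monotone and, from the uniform
  initialization, reproduces the brute-force mesh optimum on all tiny
  instances in the test suite, but global optimality on large grids is not
  guaranteed.
- **Unimodality is an assumption.** For genuinely bimodal effect
  distributions the constrained $\hat g$ bridges the modes; the `bimodal`
  scenario exists to make that failure mode easy to reproduce.
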