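---
title: "Rein-control homeostasis: model, Gaussian-process limit and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rein-control homeostasis: model, Gaussian-process limit and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reinworld)
```

## The model

`reinworld` simulates a deliberately minimal ecosystem–environment feedback
loop in the Daisyworld tradition. The state is a vector of $N_E$
*environmental variables* $E$ (unbounded; think planetary temperature,
humidity, pH) and the abundances $\alpha_j$ of $K$ *biotic components*
(species, ecotypes, populations — anything with a niche and a metabolic
by-product). Each component $j$ carries three fixed traits:

* a niche optimum $\mu_j$, drawn uniformly from the *essential range*
  $[0, R]$ on every environmental axis — the band of conditions we declare
  compatible with life;
* a bounded niche function of characteristic width $\sigma$: the
  steady-state abundance is
  $\alpha_j^\*(E) = \prod_i n\!\big((E_i - \mu_{ji})/\sigma\big)$ with
  $n$ peaking at 1 and decaying to 0 — a Gaussian by default;
* an effect vector $\omega_j$, uniform on $[-1, 1]$ per axis: the signed
  push the component exerts on each environmental variable, always
  proportional to its abundance.

The coupled dynamics are linear relaxations,

$$\tau_b\,\dot\alpha_j = \alpha_j^\*(E) - \alpha_j, \qquad
  \tau_e\,\dot E_i = P_i(t) + F_i(E), \qquad
  F_i(E) = \sum_j \omega_{ji}\,\alpha_j,$$

with $P$ an external forcing (a slow ramp is the insolation analogue, a
shock an instantaneous displacement). There are no direct biotic
interactions — no competition, no trophic links, no evolution of traits:
every interaction is mediated by the shared environment. The defaults
$R = 100$, $\sigma = 5$, effects on $[-1, 1]$ define the standard study
conditions used by every analysis and test in the package; behaviour is
invariant under joint rescaling of the effect bound (it rescales $F$ and
$P$ together) and depends on $R$ and $\sigma$ essentially only through
$R/\sigma$.

Biota are assumed to be the fastest-responding part of the system
($\tau_b \ll \tau_e$). The default operating regime therefore pins
abundances to $\alpha^\*(E)$ (`quasi_steady_biota = TRUE`) and integrates
only $E$; the full $(K + N_E)$-dimensional system remains available, and a
consistency test checks the two agree to better than 1% on the ramp
scenario when $\tau_b = \tau_e/100$.

Homeostasis appears as *rein control*: a component that pushes a variable
up, overlapping with a higher-optimum component that pushes it down, pins
the variable between them — two opposing unidirectional "reins". For two
random components the four sign assignments are equally likely, so an
opposing pair occurs with probability exactly $1/4$
(`rein_pair_probability()`). With many components the total force $F(E)$
wiggles around zero, and every downward zero crossing ($+$ to $-$, left to
right) is a stable rein-control state.

## The large-K Gaussian-field limit

At any fixed $E$, $F(E)$ is a sum of $K$ independent bounded bumps with
symmetric random signs. As $K \to \infty$ the standardised force converges
to a zero-mean stationary Gaussian random field whose covariance is the
autocorrelation of the niche function. For a Gaussian niche of width
$\sigma$ this is exactly a Gaussian kernel of width $\sigma\sqrt 2$ per
axis (`force_kernel()`); for the other families the autocorrelation is
computed by quadrature. `sample_force_field()` draws realisations on a
grid over $[0, R]^{N_E}$ by Cholesky factorisation (with relative jitter
$10^{-10}$) and evaluates them by multilinear interpolation — exact at
nodes, and within the Gaussian conditional envelope between them. On
tensor grids the product kernel factorises, so the Cholesky factor is a
Kronecker product of the per-axis factors; this keeps 2-D and 3-D
sampling cheap and is verified against the dense factorisation.

### Crossing statistics

For a stationary Gaussian process with covariance $k$, the Rice formula
gives the expected number of downward zero crossings over a length $R$ as
$R\,\sqrt{-k''(0)/k(0)}/(2\pi)$. With the $\sigma\sqrt2$ kernel this is

$$\mathbb E[\#\text{stable}] \;=\; \frac{R}{2\sqrt2\,\pi\,\sigma}
  \;\approx\; 2.25 \text{ at } R = 100,\ \sigma = 5 .$$

In $N_E$ dimensions the package evaluates the Kac–Rice expectation for
stable zeros of $N_E$ independent fields,

$$\mathbb E[\#\text{stable}] \;=\;
  \Big(\frac{R}{2\sigma\sqrt{\pi}}\Big)^{N_E} \; \mathbb E|\det G|\; q_{N_E},$$

where $G$ is an $N_E \times N_E$ matrix of iid standard normals,
$\mathbb E|\det G| = \prod_{k=1}^{N_E}\sqrt2\,\Gamma((k{+}1)/2)/\Gamma(k/2)$,
and $q_N$ is the determinant-weighted probability that all eigenvalues of
$G$ have negative real part: $q_1 = 1/2$, $q_2 = 1/4$ exactly, and
$q_3 \approx 0.099$ (estimated once by a fixed-seed Monte-Carlo and
cached). The count grows exponentially with $N_E$ (about $7.96$ at
$N_E = 2$ under the standard conditions) and depends on $R$ and $\sigma$
only through their ratio. A frequently quoted shortcut — that the
$N$-dimensional stable count is simply the $N$-th power of the 1-D count —
is *not* what independent Gaussian fields do: our Monte-Carlo census gives
$8.0 \pm 0.2$ stable points at $N_E = 2$, matching the Kac–Rice value
$7.96$ and not the squared 1-D value $5.07$. (The power law *is* exact for
separable product fields, which is what the combinatorial census test
checks.)

### Saturation with diversity

A finite population only realises the Gaussian-field crossing budget once
niches tile the essential range densely enough. Operationally we define
the diversity threshold as the $K$ beyond which the expected crossing
count is within ~5% of the limit; sweeps of the count against $K$ locate
the knee at roughly four components per effective niche support
($\sigma\sqrt{2\pi}$) per axis, which is the closed form frozen in
`threshold_K()`:

$$K^\* \;=\; 4\,\Big(\frac{R}{\sigma\sqrt{2\pi}}\Big)^{N_E}
  \;\approx\; 32 \text{ at } R=100,\ \sigma=5,\ N_E = 1 .$$

Below $K^\*$ the count rises with diversity; above it, more biodiversity
neither adds nor removes stable states.

## Niche families and shape invariance

Four response families are built in; all are rescaled internally so that
the standard deviation of the normalised response — the *characteristic
width* — equals the requested `width`, which is what makes crossing
statistics comparable across shapes:

| family | form | shape parameter (default) |
|---|---|---|
| `gaussian` | $e^{-u^2/2}$ | — |
| `skewed` | skew-normal bump, mode recentred | `skewness = 1.25` |
| `bimodal` | two Gaussians at $\pm a$, peak-normalised | `separation = 1.1` |
| `fat_tailed` | Student-t bump | `tail_exponent = 3` |

The crossing rate of the limiting field is
$\sqrt{\smallint n'^2 / \smallint n^2}\,/\,2\pi$, which width-matching
equates across families only approximately. The defaults sit where the
approximation is quantitatively accurate (within ~2% of the Gaussian rate
for the skewed family and ~1% for the bimodal one, computed analytically
from the rate integral at design time): mild skew, and mode separation
just past the bimodality threshold. Stronger shape distortion drifts away
from invariance — at `skewness = 3` the rate is ~14% high, and the
fat-tailed family (~67% high at `tail_exponent = 3`) matches only
qualitatively, which is why its tests assert monotone decay rather than
count equality.

## Dynamics, protocols and detectors

* **Integrator.** Fixed-step classical RK4 (via `deSolve`), step
  `dt = 0.01 * tau_env` by default; forward Euler is available for
  pedagogy. An order test checks the $O(h^4)$ (resp. $O(h)$) error decay.
* **Ramp scenario.** The reference ramp run uses $K = 100$, $N_E = 1$,
  $E_0 = 10$ and rate $5\times10^{-4}$ per unit time, so the forcing
  reaches $\approx 3$ force standard deviations by $t = 10^4$. The rate
  puts the system deep in the slow-forcing regime: a plateau lasts
  $\Delta P/\text{rate} \sim 10^3$ time units while a fold-to-fold
  transition (whose duration scales like $\text{rate}^{-1/3}$ near the
  saddle-node exit) takes tens, so transitions complete within a few
  percent of a plateau's duration.
* **Plateau detector.** A sliding window of duration $10\,\tau_e$; a time
  belongs to a plateau when the window it starts has an $E$-range below
  $0.5\,\sigma$. Marking window *starts* (rather than whole windows)
  keeps the accelerating pre-transition edge out of the plateau; trimming
  the first window of each run likewise removes the decelerating landing
  transient of the preceding transition, so the reported per-plateau force
  imbalance $|P+F|$ reflects the pinned state. Runs shorter than one
  window are transition pauses and are not reported as plateaus.
  Note the occupied zero of $F + P$ drifts slowly as $P$ grows, so the
  *total* excursion across a long plateau may exceed the per-window bound;
  the detector is deliberately a local (windowed) criterion.
* **Shocks.** Instantaneous displacement of $E$ at the shock time
  (default magnitude $5\sigma$ in a random direction — comfortably beyond
  typical basin widths at the standard conditions); integration then
  resumes. Settling is declared when $\|\dot E\|$ stays below
  $10^{-6} R/\tau_e$ for a full window.
* **Census numerics.** 1-D crossings are bisected to $10^{-6}R$. The N-D
  census exploits the fact that a multilinear interpolant attains its
  extrema at cell corners: exactly the cells where every component changes
  sign among its corners can contain zeros, and those are polished by
  Newton iteration on the in-cell interpolant (analytic Jacobian), then
  merged within $10^{-3}R$ and classified by Jacobian eigenvalues;
  eigenvalues with $|\mathrm{Re}| < 10^{-8}$ mark a root degenerate and
  exclude it from stable counts. For callable forces the same prefilter
  runs on a seed grid and polishing uses central finite differences
  (step $10^{-5}R$).
* **Grid resolution.** Default spacing $h = \sigma/4$, i.e. about
  $\ell/5.7$ for the kernel length scale $\ell = \sigma\sqrt2$ — fine
  enough that halving $h$ leaves crossing counts statistically unchanged.
  For $N_E = 3$ the covariance factorisation stays desk-scale by
  coarsening to $h = \sigma/2$; a warning appears beyond $\ell/2$.
* **Hysteresis.** A quasi-static sweep: at each forcing step the state
  relaxes fully before $P$ moves on, which is the zero-rate limit of the
  ramp. Jumps larger than $\sigma$ between consecutive steps are recorded
  as transitions; the loop area is the trapezoidal area between the up and
  down branches.

## What the synthetic scenarios do and do not emulate

The generator reproduces the *study conditions* — random uniform optima
and effects, matched-width niche families, slow ramps, shocks, fresh
Gaussian fields per trial — not any empirical data set. Passing tests
therefore demonstrate internal consistency of the model and its
large-$K$ theory (crossing counts, scaling laws, hysteresis topology),
and say nothing about real ecosystems: real niches are neither uniformly
placed nor independent of their effects, real forcings are not slow
ramps, and real environmental variables interact directly, not only
through the biota. The model also freezes all traits (no mutation,
adaptation or species turnover) and gives every component the same
maximum abundance.

## Problem sizes

The test-suite and acceptance analyses use: $10^5$ trials for the pair
probability; 500 field realisations per $(R, \sigma)$ setting (300 per
niche family) for 1-D crossing Monte-Carlo, each setting drawn from one
continuous RNG stream; 100 populations per $K$ for
the saturation sweep up to $K = 10^3$; 50 fields for the 2-D census; and
80/50/30 relaxation trials for the survival estimates at
$N_E = 1, 2, 3$. These sizes put Monte-Carlo standard errors a factor of
a few below the effects being tested while keeping a full run at
desk-scale.

## Known limitations

* Survival and basin estimates depend mildly on the integration step and
  the settling tolerance near basin boundaries; both are exposed.
* The bimodal family's census is exact only at the grid resolution
  contract; strongly separated modes (`separation` well above the
  default) both break width-matched invariance and demand finer grids.
* `threshold_K` is a calibrated approximation to an operational
  definition (the 5% knee), good to within a factor of ~2 across
  $R/\sigma \in [10, 40]$ where it was fixed.
* The $q_{N}$ stability fractions for $N \ge 3$ are Monte-Carlo constants,
  not closed forms.
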