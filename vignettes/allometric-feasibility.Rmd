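---
title: "Body-size scaling and the geometry of competitive coexistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Body-size scaling and the geometry of competitive coexistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allofeas)
```

## The model

`allofeas` studies communities of $|S|$ competing populations under the
generalized Lotka–Volterra competition model in carrying-capacity form,

$$\frac{\dot N_i}{N_i} = \frac{r_i}{K_i}\left(K_i - \sum_j a_{ij} N_j\right),$$

where $N_i$ is the biomass density of population $i$ (mass per area),
$r_i > 0$ its maximum intrinsic growth rate, $K_i > 0$ its carrying
capacity of biomass density, and $a_{ij} \ge 0$ the dimensionless
per-capita competitive effect of $j$ on $i$, with $a_{ii} = 1$ by
construction (each effect is measured in units of self-regulation).

Metabolic scaling theory supplies the mass dependence of every parameter.
For a fixed thermal domain and response (temperature enters only through
the scalar multiplier `fT`), the package's default laws are quarter-power:

| quantity | law | exponent |
|---|---|---|
| metabolic rate | $b_0 f_T m^{3/4}$ | $3/4$ |
| mass-specific metabolism | $b_0 f_T m^{-1/4}$ | $-1/4$ |
| max growth / mortality rate | $r_0 M^{-1/4}$ | $-1/4$ |
| generation time | $g_0 M^{1/4}$ | $1/4$ |
| biomass carrying capacity | $K_0 M^{1/4}$ | $1/4$ |
| abundance carrying capacity | $K_0 M^{-3/4}$ | $-3/4$ |
| consumption rate | $C_0 M^{-1/4}$ | $-1/4$ |

Under resource-mediated competition with fast resource dynamics the
competition coefficient is a ratio of consumption rates, which collapses
to a pure mass-ratio law:

$$a_{ij} = a_0 \left(\frac{M_j}{M_i}\right)^{-1/4}.$$

Every exponent is configurable (empirical scalings vary across taxa —
sublinear to super-linear metabolic exponents have been reported), with
the canonical quarter powers as defaults.  The mass-ratio form makes the
coefficients reciprocal, $a_{ij} a_{ji} = a_0^2$, for any mass pair.

## Feasibility geometry

Coexistence requires a *feasible* equilibrium: $N^* = A^{-1} K > 0$.
Feasibility depends on the direction of $K$, never its magnitude, so the
set of compatible carrying-capacity vectors is a convex cone — the
*feasibility domain* — spanned by the columns of $A$.  Its centroid
$K_c = (a_1 + \dots + a_{|S|})/|S|$ is the average feasible environment,
and it has a remarkable property: the equilibrium there is exactly uniform,
$N^* = (1/|S|, \dots, 1/|S|)$, independent of body size.  Dividing by mass,
the abundance density at the centroid is $I_i = h / M_i \propto M^{-1}$ —
the community-level inverse size–abundance law — regardless of the exponent
used to build $A$.

How far a candidate law $K \propto M^\beta$ sits from the centroid is
measured by the angular distance

$$d(A, K) = \arccos\frac{\langle K, K_c\rangle}{\lVert K\rVert\,\lVert K_c\rVert} \in [0^\circ, 90^\circ].$$

## The ensemble experiment

The package's central computation (`beta_sweep()`) draws an ensemble of
communities, builds each interaction matrix from its sampled masses, and
records $d(A, M^\beta)$ on a grid of exponents.  The study conditions
are the generator defaults:

* community size $S = 50$;
* masses i.i.d. lognormal with log-mean 0 and log-SD 2, i.e. spanning
  several orders of magnitude (we read the distribution's second
  parameter as an SD; the qualitative result is insensitive to this
  choice, and both parameters are configurable);
* weak-interaction normalization $a_0 = S^{-1/2}$ for $i \neq j$
  ($a_0 = 1$ on the diagonal), encoding the empirical tendency of
  interspecific effects to be weak relative to self-regulation;
* interaction exponent $\alpha = -1/4$;
* $\beta$ on a regular grid in $[-2, 2]$ (step 0.05 for figures; tests
  and examples use step 0.25).

Distances are recorded for every sampled community whether or not that
$K$ direction is feasible for it: the angle is defined for any positive
direction, and filtering would bias the ensemble mean.

```{r sweep}
cfg <- ensemble_config(S = 50, n_communities = 200, seed = 1)
bs <- beta_sweep(cfg, beta_grid = seq(-2, 2, by = 0.25))
bs
```

The mean distance is sharply minimized at $\beta = 1/4$: the
metabolically predicted quarter-power carrying-capacity law is, on
average, the direction closest to the centroid of the feasibility domain.
The minimum deepens with community size (`size_scaling()`), approaching
the centroid asymptotically for large $S$; for $S = 2$ it coincides with
the centroid only at one special value of $a_0$.

```{r sizes}
size_scaling(c(5, 25, 100), ensemble_config(n_communities = 100, seed = 1))
```

And the abundance-density consequence, as an executable check:

```{r abundance}
com <- build_interaction_matrix(sample_masses(ensemble_config(S = 20, seed = 3)))
abundance_at_centroid(com)$slope
```

## Numerical choices

* **Centroid on raw columns.**  The centroid averages the raw
  (unnormalized) columns of $A$.  Only this reading makes the uniform
  equilibrium $N^* = 1/S$ an exact algebraic identity; averaging
  unit-norm columns (common elsewhere in the structuralist literature)
  is available via `centroid(A, normalize = TRUE)` but is not the
  default.
* **Angular distance via `atan2`.**  The arccos of a clamped cosine
  loses half the working precision near collinearity (it returns
  ~$10^{-6}$ degrees for identical directions).  We evaluate the same
  angle as $2\,\mathrm{atan2}(\lVert u - v\rVert, \lVert u + v\rVert)$
  on magnitude-matched vectors, which is exact at $0^\circ$ and
  well-conditioned everywhere in $[0°, 90°]$.
* **Linear solves, never inverses.**  Equilibria are computed with
  `solve(A, K)` guarded by a reciprocal-condition-number threshold
  (condition number $10^{12}$); near-singular matrices raise an error
  rather than returning noise.  Communities that fail inside an ensemble
  are skipped and counted (`n_skipped`).
* **Feasibility tolerance.**  Feasibility is strict positivity of
  $N^*$; components in $(0, 10^{-12}]$ are flagged as boundary cases
  (e.g. $K$ equal to a column of $A$), since loss of feasibility near
  the cone's edge is an ecological-stochasticity concern, not a
  floating-point one.
* **Integration.**  `simulate_lv()` uses `deSolve::ode(method =
  "lsoda")` with `rtol` $10^{-8}$ / `atol` $10^{-10}$: wide mass ranges
  spread $r_i/K_i$ over orders of magnitude, so a stiff-capable solver
  is the safe default.  States below $10^{-12}$ are clipped to zero;
  extinction is absorbing.  Convergence to the interior equilibrium is
  asserted only after the Jacobian there is verified stable —
  feasibility alone does not imply attraction.
* **Reproducibility.**  One master seed per ensemble; per-community
  substream seeds are derived from it deterministically, so results are
  bit-identical regardless of evaluation order.
* **Problem sizes.**  The package defaults to $10^4$ communities per
  ensemble (published analyses of this geometry have used $10^4$–$10^6$).
  Examples, tests and this vignette use 100–200 communities, which
  already resolve the $\beta = 1/4$ minimum cleanly at $S = 50$; the
  acceptance checks use $S = 20$–$50$ with $n = 200$.

## Generation-time and free constants

Theory fixes only proportionalities, so several constants are free user
parameters with default 1: `g0` (generation time), the normalizations
`b0, r0, K0, C0`, and the thermal multiplier `fT`.  None of them affect
feasibility geometry — the centroid distance is invariant to the overall
scale of $K$, which is why `metabolic_K_vector()` omits $K_0$ — but they
matter for dimensional bookkeeping and for the dynamics module, where
$r_i/K_i$ sets time scales.  The mortality/growth ratio $d/r$ in the
demographic consumption law defaults to 1; only the ratio enters the
scaling result.

## What the generator does and does not emulate

The synthetic communities capture: lognormal body-size spectra spanning
orders of magnitude, mass-ratio competition with weak off-diagonal
normalization, and direction-based feasibility.  They do not capture:
trophic (consumer–resource) structure, temperature-response curvature
(only the scalar `fT`), empirical size distributions, correlated or
sparse interaction structures, or dynamical-stability filtering (a
Jacobian spot-check is provided, but communities are not screened by
stability).  Passing tests therefore demonstrate the internal geometry of
the model under its stated assumptions — not that real communities place
their carrying capacities at the centroid.

## Known limitations

* The exact two-species value of $a_0$ at which $\beta = 1/4$ hits the
  centroid exactly is not derived here; the two-species case is covered
  by a generic worked example and the analytic feasibility-cone oracle.
* The feasibility domain's normalized solid angle (the feasibility
  *volume*) is out of scope; only centroid distance and point
  feasibility are computed.
* Stability is spot-checked, never systematically analyzed.
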