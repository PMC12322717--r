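# allofeas

Allometric scaling and the feasibility of competitive communities.

`allofeas` is for theoretical community ecologists who want to connect
two bodies of theory in one executable framework: **metabolic scaling
theory**, which predicts how demographic parameters depend on body mass
through quarter-power laws, and the **structural (feasibility) approach
to coexistence**, which characterizes the carrying-capacity directions
compatible with a positive Lotka–Volterra equilibrium.

## The model

Communities of $|S|$ populations follow generalized Lotka–Volterra
competition,

$$\dot N_i / N_i = (r_i/K_i)\,(K_i - \textstyle\sum_j a_{ij} N_j),$$

with body mass $M_i$ setting every parameter: growth rate
$r_i = r_0 M_i^{-1/4}$, biomass carrying capacity $K_i = K_0 M_i^{1/4}$,
and competitive effects $a_{ij} = a_0 (M_j/M_i)^{-1/4}$ with $a_{ii}=1$
and $a_0 = |S|^{-1/2}$ (weak interspecific competition).  Coexistence
requires feasibility, $N^* = A^{-1}K > 0$, which depends only on the
*direction* of $K$; the feasible directions form a cone spanned by the
columns of $A$, whose centroid $K_c = \sum_j a_j/|S|$ is the average
feasible environment.  The package measures the angular distance
$d(A, K) = \arccos\big(\langle K, K_c\rangle / \lVert K\rVert\lVert
K_c\rVert\big)$ in degrees, and asks: for which exponent $\beta$ does
$K \propto M^\beta$ sit closest to the centroid?

The answer — computed, not assumed — is $\beta = 1/4$, the metabolically
predicted law.  At the centroid all equilibrium biomass densities are
equal ($N^*_i = 1/|S|$), so abundance density scales as $M^{-1}$: the
community-level inverse size–abundance relationship.

## Worked example

```r
library(allofeas)

cfg <- ensemble_config(S = 50, n_communities = 200, seed = 1)
bs <- beta_sweep(cfg, beta_grid = seq(-2, 2, by = 0.25))
bs
#> Carrying-capacity exponent sweep: 200 communities of S = 50
#>   grid [-2, 2] (17 values); argmin beta = 0.25 (2.049 deg)

subset(bs$summary, beta %in% c(-2, 0, 0.25, 0.5, 2))
#>  beta mean_distance_deg sd_distance_deg   n
#> -2.00            85.264           2.015 200
#>  0.00            25.253           3.111 200
#>  0.25             2.049           0.121 200
#>  0.50            24.735           4.114 200
#>  2.00            60.832           4.230 200
```

Across 200 random 50-species communities, the $K \propto M^{1/4}$
direction lies on average only ~2° from the centroid of the feasibility
domain, while every other exponent on the grid is tens of degrees away.
The minimum deepens with community size:

```r
size_scaling(c(5, 25, 100), ensemble_config(n_communities = 100, seed = 1))
#>     S mean_distance_deg sd_distance_deg   n
#> 1   5          3.236784      0.68294146 100
#> 2  25          2.588762      0.21248512 100
#> 3 100          1.561967      0.06247103 100
```

And the abundance consequence — at the centroid, equilibrium abundance
density is exactly inverse in body mass:

```r
com <- build_interaction_matrix(sample_masses(ensemble_config(S = 20, seed = 3)))
abundance_at_centroid(com)$slope
#> [1] -1
```

## Command line

A thin wrapper ships with the installed package:

```sh
$(Rscript -e 'cat(system.file("exec", "allofeas", package = "allofeas"))') \
  sweep --S 50 --n 200 --beta-step 0.25 --seed 42 --out out/
```

Commands `sweep` and `sizes` write an RFC-4180 CSV plus a JSON manifest
recording the full configuration and master seed, so every result file
is reproducible from its manifest alone.

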