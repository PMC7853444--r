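# copepodFR

Analysis of laboratory predation trials in which cyclopoid copepods
(*Macrocyclops albidus*, *Megacyclops viridis*) prey on newly-hatched
mosquito larvae — the standard screening workflow for copepods as
biological control agents against container-breeding vectors such as
*Aedes albopictus*.

## What it computes

Predation trials run in small closed arenas without prey replacement, so
prey deplete during the trial and the functional response must be fitted
through the integrated dynamics rather than the instantaneous curve. The
package implements:

* **Response-type classification** (type II vs type III) from the sign and
  significance of polynomial logistic regressions of proportional
  consumption on initial density.
* **Functional-response fitting** by binomial maximum likelihood around the
  prey-depletion equation

  ```
  dN/dt = -b N^(1+q) / (1 + b h N^(1+q)) * P - m N
  ```

  with attack coefficient `b`, handling time `h`, shape exponent
  `q ∈ {0, 1}` fixed by the classifier, predator count `P`, and background
  mortality `m` informed by predator-absent controls. The type II,
  zero-mortality case uses the Rogers random-predator closed form via the
  Lambert W function; the general case uses the exact separable solution
  (q = 0) or an adaptive ODE solver (q = 1). A Wald test decides whether
  the mortality term is retained. Profile-likelihood 95% intervals are
  computed for `b` and `h`, and groups are compared by interval overlap.
* **Predation efficiency**: Abbott's control-corrected efficiency
  `100 (C - Tr) / C` for matched treatment-control pairs, six candidate
  linear models (species or body mass, ± temperature, ± interaction)
  ranked by AIC with the ΔAIC ≥ 2 preference rule.
* **Allometry and body-size tests**: mass = 0.055 · length^2.73 (mg, mm),
  normality-gated Welch/Wilcoxon comparisons, seeded random cross-species
  pairing.
* **A synthetic-trial generator** reproducing the experimental design
  (density ladder 1–32 with 4 predator replicates + 1 control per density
  per species-temperature combination; fixed-density efficiency arm), in a
  model-matched binomial mode and an event-driven Gillespie mode.

## Worked example

```r
library(copepodFR)

# one full functional-response design at one temperature, simulated
design <- experiment_design(temperatures = 15)
cfg <- pipeline_config(seed = 14,
                       sim_config = simulation_config(design = design,
                                                      seed = 14))
res <- run_fr_analysis(cfg)
res$fr_parameters
#>          group        variant q       b    b_low  b_high        h    h_low
#> 1 M_albidus_15 with_mortality 0 1.13655 0.650122 2.06608 0.547075 0.448257
#> 2 M_viridis_15 with_mortality 0 1.17799 0.679109 2.12475 0.478509 0.398251
#>     h_high          m mortality_p deviance converged
#> 1 0.672914 0.01048815   0.0123224  84.3778      TRUE
#> 2 0.574942 0.00882627   0.0233152  68.6110      TRUE
```

Both simulated groups were generated with a type II response (`q = 0`,
`b = 1`, `h = 0.5` h, `m = 0.01` h⁻¹): the classifier fixes `q = 0`, both
groups retain the mortality term (control deaths occurred; Wald p ≈ 0.012
and 0.023), and the profile intervals for `b` and `h` bracket the
generating values. The `h` estimates read directly in hours (≈ 29–33 min
handling time here).

```r
eff <- run_efficiency_analysis(pipeline_config(seed = 1))
head(as.data.frame(eff$selection), 3)
#>                model df adjusted_R2     AIC delta_AIC preferred
#> 1          mass_only 46    0.176819 359.422   0.00000      TRUE
#> 2   mass_temperature 44    0.139625 363.410   3.98754     FALSE
#> 3 mass_x_temperature 42    0.122589 366.118   6.69576     FALSE

eff$models$mass_only$terms
#>              term estimate    se     t        p
#> 1     (Intercept)    10.84 3.586 3.023 0.004088
#> 2 copepod_mass_mg    33.07 9.928 3.331 0.001713
```

The efficiency arm was generated with a pure body-mass effect
(34.44 % per mg of copepod mass): the mass-only model wins the AIC ranking
with the runner-up more than 2 AIC units behind, and the recovered slope
(33.1 ± 9.9 % per mg) brackets the generating value.

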