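# traitdisp

Trait-dispersion null models and driver selection for eelgrass epifauna.

## What it is for

Communities of peracarid crustaceans (amphipods, isopods, tanaids) living on
eelgrass (*Zostera marina*) assemble from regional species pools through
competing filters: abiotic filtering pushes co-occurring species toward
similar trait values (*clustering*), while competition for resources or
enemy-free space spreads them apart (*overdispersion*). `traitdisp` is for
community ecologists who want to quantify where a site sits on that axis and
what environmental gradients — predation intensity, latitude, epiphyte
load, habitat structure — drive the variation.

The pipeline:

1. **Trait space** — a 13-trait mixed-type schema (ordered fecundity
   classes, continuous adult length, categorical shape/habit/motility,
   binary diet flags) and Gower distances over configurable trait subsets
   (all / diet / microhabitat) with principled missing-data handling.
2. **Dispersion** — per-site mean pairwise distance (MPD) and mean nearest
   taxon distance (MNTD), standardized against two permutation nulls:
   *independent swap* (randomizes the site-by-species matrix preserving row
   and column sums via checkerboard exchanges) and *tip shuffle* (permutes
   species labels on the distance matrix within a species pool). Standard
   effect sizes

   SES = (obs − mean(null)) / sd(null)

   are computed for every cell of the metric × algorithm × pool ×
   trait-subset grid (36 cells; 33 feasible after the diet/MNTD/tip-shuffle
   exclusion), with 999 permutations per null and full seed reproducibility.
3. **Driver selection** — 16 a priori regression models of site-level SES
   (biogeography, temperature regime, community, biodiversity, habitat,
   predation, resources), ranked by small-sample AICc; the top three models'
   predictors form a composite screened by variance inflation (VIF > 5
   removed iteratively) and reduced by AICc backward elimination, with a
   fewest-parameters rule among models within 3 AICc units. Welch t-tests
   summarize SES against zero and between oceans.
4. **Synthetic data** — a generator that emulates the two-ocean, two-margin,
   42-site × 20-plot design, a latitudinal predation gradient, and
   sequential community assembly with tunable environmental-filtering
   (`tau_filter`) and limiting-similarity (`tau_limit`) strength, so the
   whole chain is testable with known ground truth.

## Worked example

Simulate a study in which limiting similarity strengthens with predation
(`driver_recovery_scenario()` settings), compute SES_MNTD under the
tip-shuffle null in the global pool, and ask which a priori model explains
the site-level variation:

```r
library(traitdisp)

sc  <- driver_recovery_scenario()          # 42 sites, tau_limit = 20 * predation
out <- simulate_ses(sc, seed = 42, n_perm = 999)
summary(out$ses)
#>  metric   algorithm   pool trait_subset mean_ses sd_ses n_sites
#>    mntd tip_shuffle global          all     3.32   1.14      42

sub <- out$ses[out$ses$feasible, ]
ses_t_tests(sub)[1, ]
#>         test   group    mean        t df            p
#> 1 one-sample overall 3.32477 18.86682 41 8.002942e-22

predictors <- transform_predictors(out$env[match(sub$site, out$env$site), ])
sel <- select_drivers(sub$ses, predictors)
sel
#> Driver selection
#> Top a priori models:
#>           model k   aicc delta_aicc     r2
#>       predation 3  98.18      0.000 0.5933
#>  biogeography_2 5 101.19      3.015 0.6124
#>  biogeography_4 6 102.91      4.730 0.6217
#> Removed by VIF screening: latitude
#> Final model: ses ~ arcsin_predation
round(coef(sel), 3)
#>      (Intercept) arcsin_predation
#>            1.771            1.753
```

Reading the output: every site is overdispersed relative to the tip-shuffle
null (mean SES_MNTD = 3.32, one-sample t = 18.9), because the generator's
repulsive assembly is on everywhere; the selection pipeline ranks the
predation model first, the VIF rule drops latitude (collinear with
predation by construction of the gradient), and the final model recovers a
positive predation coefficient — the planted driver.

Field-style data enter the same way through CSVs: `read_trait_table()` +
`aggregate_sites()` (plot counts standardized per gram of eelgrass,
tether-based predation with moulted tethers excluded) feed
`community_matrix()` and `trait_dispersion()`, or run everything from a
YAML config with `run_all()` (see `inst/scripts/run_all.R` for a
command-line wrapper).

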