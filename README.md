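# serialmorph

Serial disparity, evolutionary constraint and ecomorphological signal along
metameric skeletal systems.

Multi-element structures such as the mammalian presacral vertebral column
evolve as a chain of serially homologous parts whose regional counts vary
across species (13 thoracics + 7 lumbars in one carnivoran, 15 + 5 in
another, with the thoracolumbar total fixed at 20). `serialmorph` is for
comparative morphologists who want to ask, vertebra by vertebra, how much
species differ in shape, how constrained each element's evolution has been,
and which locomotor capabilities shape it — while handling the homology
problem that count variation creates.

## What it computes

Given per-vertebra 3D landmark configurations, a species metadata table, a
time-calibrated phylogeny and a locomotor-capability coding, the package:

* superimposes each region by **generalized Procrustes analysis with
  object-symmetry correction** (the symmetric shape component of each
  vertebra), then averages specimens within species;
* groups vertebrae across species under two **seriation schemes** — *by
  number* (all C03, all T14, ...) and *by position* (Tfirst, Tmid, Tdiaph,
  Tlast, Lfirst, Lmid, Llast) — and computes per-group **disparity** as the
  Procrustes variance standardised by landmark count,

  `D_g = (1/n) * sum_i ||x_i - x̄||² / K`;

* quantifies **constraint** per group by disparity-through-time against a
  multivariate Brownian null: relative subclade disparity at each node age,
  summarised by the **morphological disparity index**

  `MDI = ∫₀¹ [ DTT_obs(t) - DTT_BM(t) ] dt`,

  positive when subclades overlap in morphospace (constrained evolution),
  negative when morphospace is partitioned;
* measures **ecomorphological signal** by phylogenetic Procrustes ANOVA
  with residual-randomization permutation (RRPP) on five binary locomotor
  capabilities, with exhaustive subset model selection (best total R² among
  models whose terms all reach p < 0.1) and per-capability morphological
  deviations;
* relates the per-position series of disparity, MDI and ecological R² along
  the column by **AR1 generalized least squares** (ML), accounting for the
  serial correlation of adjacent vertebrae.

A synthetic-data generator (`reference_scenario()`, `generate_columns()`)
emulates a 44-species carnivoran-like study — homeotic count variation,
constrained (Ornstein–Uhlenbeck) cervicals versus labile (Brownian)
lumbars, aquatic-dominated ecological effects — with recorded ground truth,
and writes exactly the input formats the readers consume, so the whole
pipeline runs end-to-end offline.

## Worked example

```r
library(serialmorph)

gen <- generate_columns(reference_scenario("paper_like",
                                           n_species = 16, seed = 3))
res <- run_full_analysis(gen, n_perm = 199, n_sim = 50, seed = 11)
print(res)
#> Serial-disparity analysis: 16 species, schemes: by_number, by_position
#>   by_number: disparity~MDI slope -0.0006211 (p = 0.002406) over 26 positions
#>   by_position: disparity~MDI slope 1.66e-05 (p = 0.9525) over 12 positions
```

The headline regression says that across the 26 by-number vertebral
positions, disparity and MDI are inversely related (slope < 0, p ≈ 0.002):
elements whose subclades overlap most in morphospace (high MDI, constrained
evolution) are the least disparate. At this reduced size (16 species) the
12-point by-position series is not yet significant; at the full 44-species
design both schemes agree.

```r
head(as.data.frame(res$schemes$by_number$disparity), 7)
#>   group n_species procrustes_variance standardized_disparity
#> 1   C03        16             0.00533               0.000157
#> 2   C04        16             0.00410               0.000121
#> ...
```

Disparity per group, standardised by the region's landmark count so
cervical (K = 34), thoracic (32) and lumbar (36) values are comparable.

```r
res$schemes$by_number$dtt$C05
#> Disparity-through-time: 15 node times
#>   MDI = 0.3508 (50 simulations, mean central curve)
```

A strongly positive MDI for a cervical vertebra: its subclades occupy
overlapping regions of shape space, the signature of constrained evolution.

```r
res$position_anovas$cervical
#> Procrustes ANOVA (RRPP, 199 permutations)
#>           Df     SS       MS    Rsq     F     Z Pr(>F)
#> position   4 0.5250 0.131251 0.5809 25.99 7.507  0.005
#> Residuals 75 0.3788 0.005051 0.4191
#> Total     79 0.9038
```

Serial position explains 58% of cervical shape variation (5 positions × 16
species; factor df 4), i.e. cervical vertebrae are strongly differentiated
by position.

## Vignette

`vignettes/serial-disparity-methods.Rmd` documents the statistical model,
every tunable parameter and default, the synthetic generator's assumptions
and what passing tests do and do not demonstrate, numerical edge cases, and
known limitations.
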