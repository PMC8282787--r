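Package: serialmorph
Title: Serial Disparity, Evolutionary Constraint and Ecomorphology in
    Metameric Landmark Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how morphological disparity, evolutionary
    constraint and ecological signal are distributed along serially
    homologous skeletal systems such as the mammalian presacral
    vertebral column. Provides generalized Procrustes alignment with
    object-symmetry correction, per-vertebra Procrustes-variance
    disparity under two seriation schemes ("by number" and "by
    position") for taxa with homeotic count variation,
    disparity-through-time curves and the morphological disparity
    index against a multivariate Brownian-motion null, (phylogenetic)
    Procrustes ANOVA with residual-randomization permutation and
    exhaustive capability-subset model selection, and AR1 generalized
    least-squares comparisons of per-position metrics along the
    column. Includes a synthetic-data generator that emulates a
    carnivoran-like study design with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    nlme,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
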