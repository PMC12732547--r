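Package: xelim
Title: Deterministic Dynamics of X-Chromosome Elimination and the
    Digenic-to-Monogenic Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic evolutionary population-genetics simulator for
    the transition from digenic (XX/X0) to monogenic sex determination through
    maternal imprinting and elimination of the paternal X chromosome.  Models
    an infinite panmictic population with discrete non-overlapping
    generations, tracking parent-of-origin-resolved genotype frequencies in
    each sex.  Four modifier genes are followed: a maternal inhibitor whose
    oocyte-stored product dose equals the mother's allele count, a
    spermatogenesis gene that makes sperm carry the intact maternally derived
    chromosome complement, a zygotic elimination factor that removes
    unprotected X chromosomes, and an imprinting gene that protects the
    maternal X.  Provides the genotype/gamete algebra, the zygote-resolution
    engine (two-factor, one-factor and sciarid-type X-linked variants), the
    generation recursion with viability selection and sex-ratio tracking,
    allele-introduction and equilibrium detection, brood classification
    (digenic, monogenic, mixed, extinct), a built-in scenario catalogue for
    every gene-emergence sequence, and tidy/broom-style accessors with
    ggplot2 trajectory plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
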