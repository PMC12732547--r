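# The generation recursion: fixed points, conservation, neutrality, the
# introduction protocol, and the naive full-expansion oracle.

test_that("the ancestral XX/X0 state and the monogenic state are fixed points", {
  cfg <- cfg_std()
  anc <- ancestral_population(cfg)
  nx <- next_generation(anc, cfg)
  expect_equal(freq_of(nx, "female", "XX EE SS RR gg"), 1, tolerance = 1e-12)
  expect_equal(freq_of(nx, "male", "g(X0 EE SS RR gg)"), 1, tolerance = 1e-12)
  expect_equal(sex_ratio(nx), 1, tolerance = 1e-12)

  mono <- monogenic_population(cfg)
  nx2 <- next_generation(mono, cfg)
  expect_equal(sex_ratio(nx2), 1, tolerance = 1e-12)
  for (lab in c("XX Ee ss rr gg", "XX ee ss rr gg")) {
    expect_equal(freq_of(nx2, "female", lab), 0.5, tolerance = 1e-12)
  }
  for (lab in c("g(X0 EE ss rr gg)", "g(X0 Ee ss rr gg)",
                "g(X0 eE ss rr gg)", "g(X0 ee ss rr gg)")) {
    expect_equal(freq_of(nx2, "male", lab), 0.25, tolerance = 1e-12)
  }
})

test_that("viability selection shifts the sex ratio of the heterozygote-female state to 1/0.9", {
  cfg <- cfg_std()
  pop <- pop_of(cfg,
                c("XX EE ss Rr gg" = 1), c("g(X0 EE ss rr gg)" = 1))
  nx <- next_generation(pop, cfg, selection_regime("r", "recessive"))
  expect_equal(sex_ratio(nx), 1 / 0.9, tolerance = 1e-12)
  expect_equal(freq_of(nx, "female", "XX EE ss Rr gg"), 1, tolerance = 1e-12)
  expect_equal(freq_of(nx, "male", "g(X0 EE ss rr gg)"), 1, tolerance = 1e-12)
})

test_that("allele introduction produces exact Hardy-Weinberg proportions in linkage equilibrium", {
  cfg <- cfg_std()
  pop <- introduce_allele(ancestral_population(cfg), cfg, "e", freq = 0.05)
  expect_equal(freq_of(pop, "female", "XX EE SS RR gg"), 0.9025,
               tolerance = 1e-12)
  expect_equal(freq_of(pop, "female", "XX Ee SS RR gg"), 0.095,
               tolerance = 1e-12)
  expect_equal(freq_of(pop, "female", "XX ee SS RR gg"), 0.0025,
               tolerance = 1e-12)
  # males keep parental order: the two heterozygote classes get half each
  expect_equal(freq_of(pop, "male", "g(X0 Ee SS RR gg)"), 0.0475,
               tolerance = 1e-12)
  expect_equal(freq_of(pop, "male", "g(X0 eE SS RR gg)"), 0.0475,
               tolerance = 1e-12)
  # boundary frequencies
  expect_equal(introduce_allele(ancestral_population(cfg), cfg, "e",
                                freq = 0)$genotype,
               ancestral_population(cfg)$genotype)
  p1 <- introduce_allele(ancestral_population(cfg), cfg, "e", freq = 1)
  expect_equal(freq_of(p1, "female", "XX ee SS RR gg"), 1, tolerance = 1e-12)
  expect_error(introduce_allele(ancestral_population(cfg), cfg, "z", 0.05),
               "locus")
})

test_that("a neutral allele with no functional partner is invariant under the recursion", {
  cfg <- cfg_std()
  pop <- introduce_allele(ancestral_population(cfg), cfg, "e", freq = 0.05)
  tr <- run_to_equilibrium(pop, cfg, tol = 1e-10, max_gens = 50L)
  expect_true(tr$converged)
  expect_lte(tr$generations, 2L)
  af <- allele_frequency(tr$final, cfg, "e")
  expect_equal(af$frequency, c(0.05, 0.05), tolerance = 1e-12)
  # frequencies conserved and non-negative along the way
  for (st in tr$states) {
    expect_equal(sum(st$f), 1, tolerance = 1e-12)
    expect_equal(sum(st$m), 1, tolerance = 1e-12)
    expect_true(all(st$f >= 0) && all(st$m >= 0))
  }
})

test_that("the pooled-gamete engine matches the naive full-expansion oracle", {
  cfg <- model_config(loci = c("e", "r", "g"))
  pop <- ancestral_population(cfg) |>
    introduce_allele(cfg, "e", freq = 0.05) |>
    introduce_allele(cfg, "r", freq = 0.3) |>
    introduce_allele(cfg, "g", freq = 0.2, replace = "g", allele = "G")
  v <- list(
    f = stats::setNames(pop$frequency[pop$sex == "female"],
                        pop$genotype[pop$sex == "female"]),
    m = stats::setNames(pop$frequency[pop$sex == "male"],
                        pop$genotype[pop$sex == "male"])
  )
  for (gen in 1:3) {
    naive <- naive_step_erg(v$f, v$m)
    pop <- next_generation(pop, cfg)
    got <- list(
      f = stats::setNames(pop$frequency[pop$sex == "female"],
                          pop$genotype[pop$sex == "female"]),
      m = stats::setNames(pop$frequency[pop$sex == "male"],
                          pop$genotype[pop$sex == "male"])
    )
    expect_freqs_equal(got$f, naive$f, tol = 1e-12)
    expect_freqs_equal(got$m, naive$m, tol = 1e-12)
    v <- naive
  }
})

test_that("male heterozygote classes at the inhibitor locus are symmetric at the monogenic state", {
  cfg <- cfg_std()
  nx <- next_generation(monogenic_population(cfg), cfg)
  expect_equal(freq_of(nx, "male", "g(X0 Ee ss rr gg)"),
               freq_of(nx, "male", "g(X0 eE ss rr gg)"), tolerance = 1e-14)
})

test_that("losing every male raises the extinction condition", {
  cfg <- cfg_std()
  # all females gynogenic, imprinted males with functional AB: no sons
  pop <- pop_of(cfg, c("XX ee ss rr gg" = 1), c("g(X0 ee ss rr gg)" = 1))
  expect_error(next_generation(pop, cfg), class = "xelim_extinct")
  tr <- run_to_equilibrium(pop, cfg)
  expect_equal(tr$extinct, "male")
})

test_that("removing the selection differential removes the drive-selection balance", {
  cfg <- cfg_std()
  pop <- introduce_allele(ancestral_population(cfg), cfg, "s", freq = 0.05)
  tr <- run_to_equilibrium(pop, cfg, selection_regime("s", "recessive",
                                                      mu = 0),
                           max_gens = 600L, tol = 1e-10)
  ss <- freq_of(tr$final, "female", "XX EE ss RR gg")
  # with mu = 0 the recursion does not sit at the mu = 0.1 equilibrium
  expect_gt(abs(ss - 0.378), 0.05)
})
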