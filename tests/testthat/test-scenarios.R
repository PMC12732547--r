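# Worked single-pair crosses, brood classification, and scenario stepping.

test_that("two-factor monogenic crosses reproduce the worked brood tables", {
  cfg <- cfg_std()
  cases <- list(
    # mother, father, expected offspring (label = mass), daughters fraction
    list("XX ee ss rr gg", "g(X0 EE ss rr gg)",
         c("XX Ee ss rr gg" = 1), 1),
    list("XX ee ss rr gg", "g(X0 Ee ss rr gg)",
         c("XX Ee ss rr gg" = 1), 1),
    list("XX ee ss rr gg", "g(X0 eE ss rr gg)",
         c("XX ee ss rr gg" = 1), 1),
    list("XX ee ss rr gg", "g(X0 ee ss rr gg)",
         c("XX ee ss rr gg" = 1), 1),
    list("XX Ee ss rr gg", "g(X0 EE ss rr gg)",
         c("g(X0 EE ss rr gg)" = 0.5, "g(X0 eE ss rr gg)" = 0.5), 0),
    list("XX Ee ss rr gg", "g(X0 Ee ss rr gg)",
         c("g(X0 EE ss rr gg)" = 0.5, "g(X0 eE ss rr gg)" = 0.5), 0),
    list("XX Ee ss rr gg", "g(X0 eE ss rr gg)",
         c("g(X0 Ee ss rr gg)" = 0.5, "g(X0 ee ss rr gg)" = 0.5), 0),
    list("XX Ee ss rr gg", "g(X0 ee ss rr gg)",
         c("g(X0 Ee ss rr gg)" = 0.5, "g(X0 ee ss rr gg)" = 0.5), 0)
  )
  for (cs in cases) {
    tab <- cross(cs[[1]], cs[[2]], cfg)
    got <- tapply(tab$mass, tab$offspring, sum)
    expect_freqs_equal(got, cs[[3]])
    expect_equal(attr(tab, "daughters"), cs[[4]], tolerance = 1e-12)
  }
})

test_that("one-factor monogenic crosses reproduce the worked brood tables", {
  cfg <- model_config(variant = "one_factor", loci = c("e", "s", "g"))
  cases <- list(
    list("XX EE ss gg", "g(X0 EE ss gg)", c("XX EE ss gg" = 1), 1),
    list("XX EE ss gg", "g(X0 eE ss gg)", c("XX Ee ss gg" = 1), 1),
    list("XX Ee ss gg", "g(X0 EE ss gg)",
         c("g(X0 EE ss gg)" = 0.5, "g(X0 eE ss gg)" = 0.5), 0),
    list("XX Ee ss gg", "g(X0 ee ss gg)",
         c("g(X0 Ee ss gg)" = 0.5, "g(X0 ee ss gg)" = 0.5), 0)
  )
  for (cs in cases) {
    tab <- cross(cs[[1]], cs[[2]], cfg)
    got <- tapply(tab$mass, tab$offspring, sum)
    expect_freqs_equal(got, cs[[3]])
    expect_equal(attr(tab, "daughters"), cs[[4]], tolerance = 1e-12)
  }
})

test_that("sciarid crosses: gynogenic and androgenic females split as in the presets", {
  cfg <- sciara_config("two_factor")
  gyn <- cross("InvXeX cc ss rr gg", "g(X0 cc ss rr gg)", cfg)
  got <- tapply(gyn$mass, gyn$offspring, sum)
  expect_freqs_equal(got, c("InvXeX cc ss rr gg" = 0.5,
                            "XX cc ss rr gg" = 0.5))
  andro <- cross("XX cc ss rr gg", "g(X0 cc ss rr gg)", cfg)
  expect_equal(attr(andro, "sons"), 1, tolerance = 1e-12)

  cfg1 <- sciara_config("one_factor")
  gyn1 <- cross("XeInvX cc ss gg", "g(Xe0 cc ss gg)", cfg1)
  got1 <- tapply(gyn1$mass, gyn1$offspring, sum)
  expect_freqs_equal(got1, c("XeInvX cc ss gg" = 0.5, "XeXe cc ss gg" = 0.5))
  andro1 <- cross("XeXe cc ss gg", "g(Xe0 cc ss gg)", cfg1)
  expect_equal(attr(andro1, "sons"), 1, tolerance = 1e-12)
})

test_that("population classification separates digenic, monogenic and mixed states", {
  cfg <- cfg_std()
  expect_equal(classify_population(ancestral_population(cfg), cfg)$class,
               "digenic")
  cl <- classify_population(monogenic_population(cfg), cfg)
  expect_equal(cl$class, "monogenic")
  expect_setequal(cl$females$type, c("gynogenic", "androgenic"))
  expect_equal(cl$females$type[cl$females$genotype == "XX ee ss rr gg"],
               "gynogenic")
  expect_equal(cl$females$type[cl$females$genotype == "XX Ee ss rr gg"],
               "androgenic")
  # a digenic female class alongside brood-splitting ones: mixed
  mixed <- pop_of(cfg,
    c("XX ee ss rr gg" = 0.4, "XX Ee ss rr gg" = 0.4,
      "XX EE ss Rr gg" = 0.2),
    c("g(X0 EE ss rr gg)" = 1))
  expect_equal(classify_population(mixed, cfg)$class, "mixed")
})

test_that("brood profiles match the cross tables against a male pool", {
  cfg <- cfg_std()
  mono <- monogenic_population(cfg)
  bp <- brood_profile("XX ee ss rr gg", mono, cfg)
  expect_equal(bp$daughters, 1, tolerance = 1e-12)
  bp2 <- brood_profile("XX Ee ss rr gg", mono, cfg)
  expect_equal(bp2$sons, 1, tolerance = 1e-12)
  anc <- ancestral_population(cfg)
  bp3 <- brood_profile("XX EE SS RR gg", anc, cfg)
  expect_equal(bp3$daughters, 0.5, tolerance = 1e-12)
})

test_that("scenario stepping introduces, equilibrates and records allele fates", {
  cfg <- cfg_std()
  sc <- scenario("drive-balance", cfg, ancestral_population(cfg),
                 list(stage("s", selection = "joint")))
  res <- run_scenario(sc, tol = 1e-8)
  td <- tidy(res)
  expect_equal(td$fate, "polymorphic")
  expect_equal(td$class, "digenic")
  expect_lt(abs(td$sex_ratio - 0.62), 5e-3)
  expect_false(glance(res)$monogenic)
})

test_that("the catalogue expands every group into runnable scenarios", {
  scns <- scenario_catalogue()
  expect_length(scns, 41L)
  expect_true(all(c("1A_esr", "1D_rse", "NI_sre", "ACQ_gsr", "ESTAR_dom",
                    "OF_es", "1B_rs_carry") %in% names(scns)))
  for (sc in scns) {
    expect_s3_class(sc, "xelim_scenario")
    expect_s3_class(sc$initial, "xelim_population")
    expect_gte(length(sc$stages), 1L)
  }
})
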