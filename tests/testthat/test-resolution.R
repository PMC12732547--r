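# The zygote-resolution engine: dose arithmetic, protection, and the
# brute-force removal oracle.

zyg <- function(cfg, mother, father_hap, x_sperm = TRUE) {
  eggs <- oogenesis(mother, cfg)
  sp <- spermatogenesis(father_hap, cfg)
  fertilize(eggs[1, ], sp[sp$x_content == (if (x_sperm) 1L else 0L), ][1, ],
            cfg)
}

test_that("elimination dose is all-or-nothing per the zygote's r genotype", {
  cfg <- cfg_std()
  z_rr <- zyg(cfg, "XX Ee ss rr gg", "g(X0 eE ss rr gg)")
  expect_equal(r_dose(z_rr, cfg), 2L)
  z_Rr <- zyg(cfg, "XX Ee ss Rr gg", "g(X0 eE ss rr gg)")
  # the maternal allele can be R or r depending on the egg row; force both
  eggs <- oogenesis("XX EE ss Rr gg", cfg)
  sp <- spermatogenesis("g(X0 EE ss rr gg)", cfg)
  for (i in seq_len(nrow(eggs))) {
    z <- fertilize(eggs[i, ], sp[1, ], cfg)
    expected <- if (grepl(" r ", paste0(" ", eggs$haplotype[i], " "))) 2L
                else 0L
    expect_equal(r_dose(z, cfg), expected)
  }
  cfg_dom <- cfg_std(dominance = c(s = "recessive", r = "dominant"))
  z_dom <- zyg(cfg_dom, "XX EE SS Rr GG", "X0 EE SS rr GG")
  expect_equal(r_dose(z_dom, cfg_dom), 2L)  # heterozygote functional
})

test_that("inactivation capacity is one per [e] dose and two per [e*] dose", {
  cfg <- cfg_std(estar = TRUE)
  z2 <- zyg(cfg, "XX ee ss rr gg", "g(X0 EE ss rr gg)")
  expect_equal(inactivation_capacity(z2), 2L)
  z0 <- zyg(cfg, "XX EE ss rr gg", "g(X0 EE ss rr gg)")
  expect_equal(inactivation_capacity(z0), 0L)
  zs <- zyg(cfg, "XX Ee* ss rr gg", "g(X0 EE ss rr gg)")
  expect_equal(inactivation_capacity(zs), 2L)
})

test_that("worked zygote fates resolve as in the cross figures", {
  cfg <- cfg_std()
  # gynogenic mother: two doses neutralise the factor, daughter keeps Xp
  r <- resolve_zygote(zyg(cfg, "XX ee ss rr gg", "g(X0 EE ss rr gg)"), cfg)
  expect_equal(r$result, "XX Ee ss rr gg")
  expect_equal(r$mass, 1)
  # androgenic mother: one residual dose removes the paternal X
  eggs <- oogenesis("XX Ee ss rr gg", cfg)
  sp <- spermatogenesis("g(X0 EE ss rr gg)", cfg)
  eggE <- eggs[eggs$haplotype == "E s r g", ]
  r2 <- resolve_zygote(fertilize(eggE, sp[1, ], cfg), cfg)
  expect_equal(r2$result, "g(X0 EE ss rr gg)")
  expect_equal(r2$sex, "male")
  # protected X0 zygote: idle doses are harmless, male unchanged
  zm <- zyg(cfg, "XX EE ss rr gg", "X0 EE ss rr gg", x_sperm = FALSE)
  rm <- resolve_zygote(zm, cfg)
  expect_equal(rm$sex, "male")
  expect_equal(rm$mass, 1)
  # without imprinting both X of an XX zygote are removed: death
  cfgn <- cfg_std(loci = c("e", "s", "r"))
  zf <- zyg(cfgn, "XX EE ss rr", "X0 EE ss rr", x_sperm = TRUE)
  rf <- resolve_zygote(zf, cfgn)
  expect_equal(rf$result, "dead")
  expect_equal(rf$mass, 1)
  # and an unprotected X0 zygote dies too
  z0 <- zyg(cfgn, "XX EE ss rr", "X0 EE ss rr", x_sperm = FALSE)
  expect_equal(resolve_zygote(z0, cfgn)$result, "dead")
})

test_that("one-factor model: the maternal dose itself removes unprotected X chromosomes", {
  cfg <- model_config(variant = "one_factor", loci = c("e", "s", "g"))
  # no dose, no elimination
  r0 <- resolve_zygote(zyg(cfg, "XX EE ss gg", "g(X0 eE ss gg)"), cfg)
  expect_equal(r0$result, "XX Ee ss gg")
  # one dose removes the paternal X
  eggs <- oogenesis("XX Ee ss gg", cfg)
  sp <- spermatogenesis("g(X0 EE ss gg)", cfg)
  eggE <- eggs[eggs$haplotype == "E s g", ]
  r1 <- resolve_zygote(fertilize(eggE, sp[1, ], cfg), cfg)
  expect_equal(r1$result, "g(X0 EE ss gg)")
})

test_that("sciarid triple-X zygotes lose paternal copies first", {
  cfg <- sciara_config("two_factor")
  eggs <- oogenesis("XX cc ss rr gg", cfg)       # androgenic, 0[e]
  sp <- spermatogenesis("g(X0 cc ss rr gg)", cfg)
  r <- resolve_zygote(fertilize(eggs[1, ], sp[1, ], cfg), cfg)
  expect_equal(r$result, "g(X0 cc ss rr gg)")    # both paternal X removed
  eggs2 <- oogenesis("InvXeX cc ss rr gg", cfg)  # gynogenic, 1[e]
  for (i in 1:2) {
    r2 <- resolve_zygote(fertilize(eggs2[i, ], sp[1, ], cfg), cfg)
    expect_equal(r2$sex, "female")               # one removal, XX survivor
  }
})

test_that("resolution agrees with the brute-force uniform-removal oracle", {
  cfg <- cfg_std()
  eggs_all <- list()
  for (mom in c("XX EE SS RR GG", "XX Ee ss rr gg", "XX ee ss rr gg",
                "XX Ee Ss Rr Gg", "XX ee SS rr GG")) {
    eg <- oogenesis(mom, cfg)
    for (i in seq_len(nrow(eg))) eggs_all[[length(eggs_all) + 1L]] <- eg[i, ]
  }
  sperm_all <- list()
  for (dad in c("X0 EE SS RR GG", "g(X0 eE ss rr gg)", "X0 Ee Ss Rr Gg")) {
    sp <- spermatogenesis(dad, cfg)
    for (i in seq_len(nrow(sp))) sperm_all[[length(sperm_all) + 1L]] <- sp[i, ]
  }
  for (eg in eggs_all) {
    for (sp in sperm_all) {
      z <- fertilize(eg, sp, cfg)
      out <- resolve_zygote(z, cfg)
      act <- max(0L, r_dose(z, cfg) - inactivation_capacity(z))
      oracle <- brute_remove(1L, sp$x_content, eg$imprint_mark, act)
      # compare mass by survivor X count
      for (k in names(oracle)) {
        cnt <- as.integer(strsplit(k, " ")[[1]])
        sel <- if (sum(cnt) == 0L) out$result == "dead"
          else if (sum(cnt) == 2L) out$sex %in% "female"
          else if (cnt[1] == 1L) out$sex %in% "male" & grepl("X0", out$result)
          else out$sex %in% "male" & grepl("0X", out$result)
        expect_equal(sum(out$mass[sel]), unname(oracle[[k]]),
                     tolerance = 1e-12)
      }
      expect_equal(sum(out$mass), 1, tolerance = 1e-12)
    }
  }
})

test_that("protection and monotonicity hold across all dose combinations", {
  cfg <- cfg_std()
  eggs <- oogenesis("XX Ee Ss Rr Gg", cfg)  # unmarked (Gg not imprinting)
  eggs_m <- oogenesis("XX Ee Ss Rr gg", cfg)
  sp <- spermatogenesis("X0 Ee Ss Rr Gg", cfg)
  x_removed <- function(out) {
    sum(out$mass[out$result == "dead"]) * 2 + sum(out$mass[out$sex %in% "male"])
  }
  for (i in seq_len(nrow(eggs_m))) {
    for (j in seq_len(nrow(sp))) {
      # a marked maternal X is never removed, whatever the doses
      z <- fertilize(eggs_m[i, ], sp[j, ], cfg)
      for (de in 0:2) {
        z$de <- de
        out <- resolve_zygote(z, cfg)
        expect_true(all(out$result != "dead"))
        expect_true(all(is.na(out$sex) | out$sex == "female" |
                          grepl("X0", out$result)))
      }
      # more capacity never removes more X chromosomes
      zu <- fertilize(eggs[i, ], sp[j, ], cfg)
      removed <- vapply(0:2, function(de) {
        zu$de <- de
        x_removed(resolve_zygote(zu, cfg))
      }, 0)
      expect_true(all(diff(removed) <= 1e-12))
      # identity case: capacity >= dose leaves the constitution unchanged
      zi <- fertilize(eggs_m[i, ], sp[j, ], cfg)
      zi$de <- 2
      out <- resolve_zygote(zi, cfg)
      expect_equal(nrow(out), 1L)
      expect_equal(out$sex, if (sp$x_content[j] == 1L) "female" else "male")
    }
  }
})
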