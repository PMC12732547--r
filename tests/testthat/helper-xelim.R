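# Shared fixtures and independent naive oracles used by the property tests.
# The oracles re-derive the model's rules in plain enumeration code so the
# engine's pooled/memoised path is checked against an implementation that
# shares nothing with it beyond the label grammar.

cfg_std <- function(...) model_config(...)

pop_of <- function(config, females, males) {
  population(tibble::tibble(
    sex = c(rep("female", length(females)), rep("male", length(males))),
    genotype = c(names(females), names(males)),
    frequency = c(unname(females), unname(males))
  ), config)
}

# ---- brute-force X-removal oracle ----------------------------------------
# uniform choice among the individually removable X chromosomes at every
# step; returns the distribution over (maternal X count, paternal X count)
brute_remove <- function(nm, np, mark, act) {
  if (act == 0L) {
    return(stats::setNames(1, paste(nm, np)))
  }
  targets <- c(rep("p", np), if (!mark) rep("m", nm))
  if (length(targets) == 0L) {
    return(stats::setNames(1, paste(nm, np)))
  }
  out <- new.env(parent = emptyenv())
  for (tg in targets) {
    sub <- if (tg == "p") brute_remove(nm, np - 1L, mark, act - 1L)
           else brute_remove(nm - 1L, np, mark, act - 1L)
    for (k in names(sub)) {
      out[[k]] <- (if (is.null(out[[k]])) 0 else out[[k]]) +
        sub[[k]] / length(targets)
    }
  }
  ks <- ls(out)
  stats::setNames(vapply(ks, function(k) out[[k]], 0), ks)
}

# ---- naive one-generation oracle -----------------------------------------
# independent full expansion of every (mother, father, egg, sperm, fate)
# tuple for the two-factor model with loci (e, r, g), g recessive and no
# spermatogenesis locus (males segregate Mendelian X/0)
naive_parse <- function(lab) {
  imprinted <- grepl("^g\\(", lab)
  raw <- sub("^g\\((.*)\\)$", "\\1", lab)
  parts <- strsplit(raw, " ")[[1]]
  list(
    male = parts[1] %in% c("X0", "0X"),
    x_pat = parts[1] == "0X",
    imprinted = imprinted,
    e = strsplit(parts[2], "")[[1]],
    r = strsplit(parts[3], "")[[1]],
    g = strsplit(parts[4], "")[[1]]
  )
}

naive_label <- function(male, e, r, g, imprinted = FALSE, x_pat = FALSE) {
  srt <- function(pr) paste(pr[order(match(pr, c("E", "e", "R", "r",
                                                 "G", "g")))], collapse = "")
  if (male) {
    lab <- paste(if (x_pat) "0X" else "X0", paste(e, collapse = ""),
                 paste(r, collapse = ""), paste(g, collapse = ""))
    if (imprinted) paste0("g(", lab, ")") else lab
  } else {
    paste("XX", srt(e), srt(r), srt(g))
  }
}

naive_step_erg <- function(f, m) {
  accF <- new.env(parent = emptyenv())
  accM <- new.env(parent = emptyenv())
  add <- function(env, lab, w) {
    env[[lab]] <- (if (is.null(env[[lab]])) 0 else env[[lab]]) + w
  }
  for (ml in names(f)) {
    mo <- naive_parse(ml)
    dose <- sum(mo$e == "e")
    mark <- all(mo$g == "g")
    for (fl in names(m)) {
      fa <- naive_parse(fl)
      w0 <- f[[ml]] * m[[fl]]
      for (ie in 1:2) for (ir in 1:2) for (ig in 1:2) {        # egg
        for (je in 1:2) for (jr in 1:2) for (jg in 1:2) {      # sperm alleles
          for (sx in c(TRUE, FALSE)) {                         # X-bearing?
            w <- w0 / 128
            ze <- c(mo$e[ie], fa$e[je])
            zr <- c(mo$r[ir], fa$r[jr])
            zg <- c(mo$g[ig], fa$g[jg])
            act <- max(0L, (if (all(zr == "r")) 2L else 0L) - dose)
            npat <- if (sx) 1L else 0L
            fate <- brute_remove(1L, npat, mark, act)
            for (k in names(fate)) {
              cnt <- as.integer(strsplit(k, " ")[[1]])
              wk <- w * fate[[k]]
              if (sum(cnt) == 0L) {
                # dead mass is lost
              } else if (sum(cnt) == 2L) {
                add(accF, naive_label(FALSE, ze, zr, zg), wk)
              } else {
                add(accM, naive_label(TRUE, ze, zr, zg, imprinted = mark,
                                      x_pat = cnt[1] == 0L), wk)
              }
            }
          }
        }
      }
    }
  }
  norm <- function(env) {
    ks <- ls(env)
    v <- stats::setNames(vapply(ks, function(k) env[[k]], 0), ks)
    v / sum(v)
  }
  list(f = norm(accF), m = norm(accM))
}

expect_freqs_equal <- function(a, b, tol = 1e-12) {
  labs <- union(names(a), names(b))
  av <- stats::setNames(numeric(length(labs)), labs); av[names(a)] <- a
  bv <- stats::setNames(numeric(length(labs)), labs); bv[names(b)] <- b
  expect_lt(max(abs(av - bv)), tol)
}

freq_of <- function(pop, sex, label) {
  hit <- pop$frequency[pop$sex == sex & pop$genotype == label]
  if (length(hit) == 0L) 0 else hit
}
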