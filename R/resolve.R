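# Zygote resolution: from a fertilised egg plus its cytoplasmic doses to an
# adult genotype, a mass split among outcomes, or death.
#
# Two-factor model: the zygote's elimination-factor supply is two doses
# whenever its r genotype is functional (the factor's quantity is the same
# in every embryo), zero otherwise; each cytoplasmic dose of [e] inactivates
# one dose, each dose of [e*] two.  The remaining active doses each remove
# one unprotected X chromosome.  One-factor model: the cytoplasmic [e] dose
# itself removes unprotected X chromosomes, one per dose.
#
# Protection: when the egg was imprint-marked, every maternally contributed
# X is immune.  Paternal X copies are removed first; if the maternal and a
# paternal X are both unprotected and one must go, the mass is split 1/2:1/2
# (a deterministic stand-in for a random target).  Autosomal alleles are
# never touched.  Survivors with two X chromosomes are females, with one are
# males (parent of origin of the retained X is recorded), with none are
# dead.  Unused doses are harmless.

new_zygote <- function(mx, px, al, de, ds, mark) {
  structure(list(mx = mx, px = px, al = al, de = de, ds = ds, mark = mark),
            class = "xelim_zygote")
}

#' Fuse an egg class and a sperm class into a zygote
#'
#' @param egg One row of an [oogenesis()] tibble (or an internal egg class).
#' @param sperm One row of a [spermatogenesis()] tibble.
#' @param config Model configuration.
#' @return An `xelim_zygote`: maternal and paternal X token sets, ordered
#'   autosomal allele pairs, cytoplasmic doses and the maternal protection
#'   flag copied from the egg.
#' @export
fertilize <- function(egg, sperm, config) {
  eg <- as_egg(egg, config)
  sp <- as_sperm(sperm, config)
  al <- list()
  for (l in aut_loci(config)) al[[l]] <- c(eg$al[[l]], sp$al[[l]])
  new_zygote(mx = eg$x, px = rep(sp$x, sp$xn), al = al,
             de = eg$de, ds = eg$ds, mark = eg$mark)
}

as_egg <- function(egg, config) {
  if (is.data.frame(egg)) {
    stopifnot(nrow(egg) == 1L)
    al <- strsplit(egg$haplotype, "\\s+")[[1]]
    list(x = egg$x, al = stats::setNames(al, aut_loci(config)),
         de = egg$cytoplasm_e, ds = egg$cytoplasm_estar,
         mark = egg$imprint_mark, p = egg$probability)
  } else egg
}

as_sperm <- function(sperm, config) {
  if (is.data.frame(sperm)) {
    stopifnot(nrow(sperm) == 1L)
    al <- strsplit(sperm$haplotype, "\\s+")[[1]]
    list(xn = sperm$x_content, x = sperm$x,
         al = stats::setNames(al, aut_loci(config)), p = sperm$probability)
  } else sperm
}

#' Elimination-factor dose of a zygote (two-factor model)
#'
#' Two doses whenever the zygote's r genotype is functional under the
#' configured dominance, zero otherwise: the factor's quantity is taken to
#' be the same in every embryo that makes it at all.
#'
#' @param zygote An `xelim_zygote`.
#' @param config Model configuration (two-factor).
#' @return Integer dose, 0 or 2.
#' @export
r_dose <- function(zygote, config) {
  stopifnot(config$variant == "two_factor")
  if (!"r" %in% config$loci) return(0L)
  if (is_functional(zygote$al[["r"]], config$dominance[["r"]], "r")) 2L else 0L
}

#' Inactivation capacity of a zygote's cytoplasm (two-factor model)
#'
#' One dose of `[e]` inactivates one dose of the elimination factor; one
#' dose of `[e*]` inactivates two.
#'
#' @param zygote An `xelim_zygote`.
#' @return Integer capacity.
#' @export
inactivation_capacity <- function(zygote) {
  as.integer(zygote$de + 2L * zygote$ds)
}

# recursive removal of `act` unprotected X chromosomes; returns list of
# list(nm, np, mass)
remove_x <- function(nm, np, mark, act, mass = 1) {
  if (act <= 0L) return(list(list(nm = nm, np = np, mass = mass)))
  mat_removable <- !mark && nm > 0L
  if (np > 0L && !mat_removable) {
    remove_x(nm, np - 1L, mark, act - 1L, mass)
  } else if (np == 0L && mat_removable) {
    remove_x(nm - 1L, 0L, mark, act - 1L, mass)
  } else if (np > 0L && mat_removable) {
    c(remove_x(nm, np - 1L, mark, act - 1L, mass / 2),
      remove_x(nm - 1L, np, mark, act - 1L, mass / 2))
  } else {
    list(list(nm = nm, np = np, mass = mass)) # nothing removable; doses idle
  }
}

#' Resolve a zygote into adults, a mass split, or death
#'
#' Computes the number of active elimination doses (two-factor: elimination
#' dose minus inactivation capacity; one-factor: the cytoplasmic `[e]`
#' dose), removes that many unprotected X chromosomes (paternal copies
#' first; a 1/2:1/2 mass split when the unprotected maternal X and a
#' paternal X are interchangeable targets), and classifies each survivor:
#' two X chromosomes make a female, one makes a male whose retained-X origin
#' and imprinting state are recorded, none is death.  Triple-X survivors are
#' not a modelled adult class and raise an error.
#'
#' @param zygote An `xelim_zygote`.
#' @param config Model configuration.
#' @return A tibble with columns `result` (genotype label or `"dead"`),
#'   `sex` (`"female"`, `"male"` or `NA`), and `mass`; masses sum to 1.
#' @export
resolve_zygote <- function(zygote, config) {
  out <- resolve_classes(zygote, config)
  tibble::tibble(
    result = vapply(out, function(o) o$label, ""),
    sex = vapply(out, function(o) o$sex, ""),
    mass = vapply(out, function(o) o$mass, 0)
  )
}

resolve_classes <- function(zygote, config) {
  act <- if (config$variant == "two_factor") {
    max(0L, r_dose(zygote, config) - inactivation_capacity(zygote))
  } else {
    as.integer(zygote$de)
  }
  nm0 <- length(zygote$mx)
  np0 <- length(zygote$px)
  fates <- remove_x(nm0, np0, zygote$mark, act)
  out <- lapply(fates, function(f) {
    n <- f$nm + f$np
    if (n == 0L) {
      return(list(label = "dead", sex = NA_character_, mass = f$mass))
    }
    if (n >= 3L) {
      stop("triple-X survivor: not a modelled adult class ",
           "(inactivation capacity exceeded elimination in a 3-X zygote)",
           call. = FALSE)
    }
    alleles <- zygote$al
    if (n == 2L) {
      sex <- "female"
      if (config$e_linkage == "X") {
        xs <- c(rep(zygote$mx, f$nm), rep(zygote$px[1], f$np))
        alleles[["e"]] <- xs
      }
      alleles <- alleles[intersect(config$loci, names(alleles))]
      ind <- new_genotype("female", canonical_female(alleles, config))
    } else {
      sex <- "male"
      origin <- if (f$nm == 1L) "maternal" else "paternal"
      if (config$e_linkage == "X") {
        tok <- if (f$nm == 1L) zygote$mx[1] else zygote$px[1]
        alleles[["e"]] <- if (origin == "maternal") c(tok, NA) else c(NA, tok)
      }
      alleles <- alleles[intersect(config$loci, names(alleles))]
      ind <- new_genotype("male", alleles, imprinted = zygote$mark,
                          x_origin = origin)
    }
    list(label = format_genotype(ind, config), sex = sex, mass = f$mass)
  })
  # collapse identical outcomes
  keys <- vapply(out, function(o) o$label, "")
  if (anyDuplicated(keys)) {
    out <- unname(lapply(split(out, keys), function(grp) {
      o <- grp[[1]]
      o$mass <- sum(vapply(grp, function(g) g$mass, 0))
      o
    }))
  }
  out
}

# memoised resolution keyed by egg class x sperm class
resolve_pair <- function(eg, sp, config) {
  key <- paste0(config$sig, "\r", egg_key(eg), "\r", sperm_key(sp))
  env <- cache_env("resolve")
  hit <- env[[key]]
  if (!is.null(hit)) return(hit)
  z <- fertilize(eg, sp, config)
  out <- resolve_classes(z, config)
  env[[key]] <- out
  out
}
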