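#' Model configuration
#'
#' Builds the configuration object shared by every operation in the package:
#' which modifier loci exist, their allele alphabets, their functional
#' dominance, the model variant, and the sciarid-type extensions.
#'
#' The loci are drawn from the canonical five:
#' * `e` — maternal inhibitor; its product is stored in the oocyte and the
#'   dose equals the mother's count of `e` alleles (dosage locus, never a
#'   simple dominant/recessive switch).  The enhanced allele `e*` inactivates
#'   two doses of the elimination factor per dose.
#' * `s` — spermatogenesis modifier; when functional in a father the
#'   maternally and paternally derived chromosome complements segregate
#'   intact instead of mixing.
#' * `r` — zygotic elimination factor; when the zygote is functional the
#'   embryo carries a full two-dose supply of the factor, the same in every
#'   embryo.
#' * `g` — maternal imprinting; a functionally imprinting mother marks her
#'   eggs so that the maternal X (and, in her sons, the whole maternal
#'   complement during spermatogenesis) is protected from elimination.
#' * `c` — sciarid chromatid non-disjunction; when functional in a father his
#'   X-bearing sperm deliver two identical copies of the X.
#'
#' @param variant `"two_factor"` (elimination factor `[r]` inhibited by the
#'   maternal factor `[e]`) or `"one_factor"` (the maternal factor itself
#'   removes unprotected X chromosomes, one per dose).
#' @param loci Character vector (ordered for display), subset of
#'   `c("e", "s", "r", "g", "c")`.
#' @param dominance Named character vector giving the functional dominance
#'   (`"recessive"` or `"dominant"`) of the switch-like loci `s`, `r`, `g`,
#'   `c`.  Locus `e` is always a dosage locus.
#' @param estar Logical; include the enhanced allele `e*` in the `e` allele
#'   alphabet (stoichiometry one dose of `[e*]` inactivates two of `[r]`).
#' @param e_linkage `"autosomal"` (default) or `"X"`; X linkage of `e` is the
#'   sciarid configuration, in which the `e` allele travels with its X
#'   chromosome.
#' @param sciara Logical; enable the sciarid preset semantics (gene `c`,
#'   double-X sperm, triple-X zygotes resolved by removing paternal copies
#'   first).
#' @param x_alleles For X-linked `e`: character vector of X-chromosome
#'   tokens, each `"E"` or `"e"` optionally suffixed `"|Inv"` to mark the
#'   inversion-bearing chromosome.  The first token is the ancestral state.
#' @param mu Default selection coefficient used when a [selection_regime()]
#'   entry does not give its own.
#'
#' @return An object of class `xelim_config`.
#' @seealso [sciara_config()] for the sciarid presets,
#'   [ancestral_population()] for the matching starting states.
#' @examples
#' cfg <- model_config()
#' cfg
#' @export
model_config <- function(variant = c("two_factor", "one_factor"),
                         loci = c("e", "s", "r", "g"),
                         dominance = c(s = "recessive", r = "recessive",
                                       g = "recessive", c = "recessive"),
                         estar = FALSE,
                         e_linkage = c("autosomal", "X"),
                         sciara = FALSE,
                         x_alleles = NULL,
                         mu = 0.1) {
  variant <- match.arg(variant)
  e_linkage <- match.arg(e_linkage)
  loci <- match.arg(loci, c("e", "s", "r", "g", "c"), several.ok = TRUE)
  if (variant == "one_factor" && "r" %in% loci) {
    stop("the one-factor model has no elimination-factor locus 'r'",
         call. = FALSE)
  }
  dom_full <- c(s = "recessive", r = "recessive", g = "recessive",
                c = "recessive")
  dom_full[names(dominance)] <- unname(dominance)
  if (!all(dom_full %in% c("recessive", "dominant"))) {
    stop("dominance entries must be 'recessive' or 'dominant'", call. = FALSE)
  }
  if (e_linkage == "X" && is.null(x_alleles)) {
    x_alleles <- c("E", "e")
  }
  alleles <- list()
  for (l in loci) {
    alleles[[l]] <- switch(l,
      e = if (e_linkage == "X") x_alleles
          else if (estar) c("E", "e", "e*") else c("E", "e"),
      s = c("S", "s"), r = c("R", "r"), g = c("G", "g"), c = c("C", "c"))
  }
  cfg <- structure(list(
    variant = variant,
    loci = loci,
    alleles = alleles,
    dominance = dom_full,
    e_linkage = e_linkage,
    sciara = isTRUE(sciara),
    mu = mu
  ), class = "xelim_config")
  cfg$sig <- paste(variant, paste(loci, collapse = ""),
                   paste(dom_full, collapse = ""), e_linkage,
                   cfg$sciara, paste(unlist(alleles), collapse = ""),
                   sep = "/")
  cfg
}

#' Sciarid-type preset configurations
#'
#' In *Sciara* the maternal-inhibitor gene sits on the X chromosome (the
#' inversion-bearing X of gynogenic females), sperm deliver the two attached
#' chromatids of the father's X (gene `c`), and zygotes therefore start with
#' three X chromosomes.  The two-factor preset puts the `e` allele on the
#' inverted X; the one-factor preset puts it on the standard X, with the
#' inverted chromosome carrying the inert allele.
#'
#' @param variant `"two_factor"` or `"one_factor"`.
#' @return An `xelim_config`.
#' @export
sciara_config <- function(variant = c("two_factor", "one_factor")) {
  variant <- match.arg(variant)
  if (variant == "two_factor") {
    model_config(variant = "two_factor", loci = c("e", "c", "s", "r", "g"),
                 e_linkage = "X", sciara = TRUE,
                 x_alleles = c("E", "e|Inv"))
  } else {
    model_config(variant = "one_factor", loci = c("e", "c", "s", "g"),
                 e_linkage = "X", sciara = TRUE,
                 x_alleles = c("e", "E|Inv"))
  }
}

#' @export
print.xelim_config <- function(x, ...) {
  cat("<xelim_config> ", x$variant,
      if (x$sciara) " (sciarid preset)", "\n", sep = "")
  for (l in x$loci) {
    cat("  locus ", l, ": alleles {",
        paste(x$alleles[[l]], collapse = ", "), "}",
        if (l %in% c("s", "r", "g", "c")) paste0(" [", x$dominance[[l]], "]"),
        if (l == "e") paste0(" [dosage, ", x$e_linkage, "]"),
        "\n", sep = "")
  }
  invisible(x)
}

# loci whose alleles segregate independently of the X
aut_loci <- function(config) {
  if (config$e_linkage == "X") setdiff(config$loci, "e") else config$loci
}

# strip the inversion marker off an X token
base_allele <- function(a) sub("\\|Inv$", "", a)

# functional test for a switch locus: dominant needs one derived copy,
# recessive needs all copies derived; NA slots (hemizygous X) are dropped
is_functional <- function(pair, dominance, derived) {
  pair <- base_allele(pair[!is.na(pair)])
  if (length(pair) == 0L) return(FALSE)
  if (dominance == "dominant") any(pair == derived) else all(pair == derived)
}

#' Viability selection regime
#'
#' A selection regime is a set of per-locus viability entries.  An individual
#' that carries the favoured allele in the configured fitness dominance sense
#' (one copy when dominant, homozygous when recessive) has fitness 1 for that
#' entry; everyone else has `1 - mu`.  Total fitness is the product over
#' entries, and an empty regime means neutrality.  Selection acts on the
#' adults of both sexes identically.
#'
#' @param locus Character vector of loci under selection.
#' @param dominance Fitness dominance per entry (`"recessive"` or
#'   `"dominant"`), recycled.
#' @param mu Selection coefficient per entry (default 0.1), recycled.
#' @param allele Favoured allele per entry; defaults to the lowercase derived
#'   allele of the locus.
#' @return A tibble of class `xelim_selection`.
#' @examples
#' selection_regime("s", "recessive")
#' selection_regime() # neutral
#' @export
selection_regime <- function(locus = character(), dominance = "recessive",
                             mu = 0.1, allele = NULL) {
  n <- length(locus)
  if (is.null(allele)) allele <- locus
  out <- tibble::tibble(locus = locus,
                        allele = rep_len(allele, n),
                        dominance = rep_len(dominance, n),
                        mu = rep_len(mu, n))
  class(out) <- c("xelim_selection", class(out))
  out
}

regime_sig <- function(regime) {
  if (is.null(regime) || nrow(regime) == 0L) return("neutral")
  paste(regime$locus, regime$allele, regime$dominance, regime$mu,
        sep = ":", collapse = "|")
}

bind_regimes <- function(...) {
  rs <- Filter(Negate(is.null), list(...))
  rs <- Filter(function(r) nrow(r) > 0L, rs)
  if (length(rs) == 0L) return(selection_regime())
  out <- dplyr::distinct(dplyr::bind_rows(rs))
  class(out) <- c("xelim_selection", class(out))
  out
}

# fitness of one parsed genotype under a regime
fitness_w <- function(ind, regime, config) {
  if (is.null(regime) || nrow(regime) == 0L) return(1)
  w <- 1
  for (k in seq_len(nrow(regime))) {
    l <- regime$locus[[k]]
    pair <- ind$alleles[[l]]
    carries <- is_functional(pair, regime$dominance[[k]], regime$allele[[k]])
    if (!carries) w <- w * (1 - regime$mu[[k]])
  }
  w
}
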