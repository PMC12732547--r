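# Brood composition and population-level outcome classification.
#
# A female is gynogenic when her brood against the current male pool is all
# daughters, androgenic when it is all sons.  A population is monogenic
# when every (fertile) female class present produces a single-sex brood and
# both brood directions coexist; digenic when no female class is
# single-sex; mixed otherwise.

#' Brood profile of a female against a male pool
#'
#' Resolves every offspring of the mother against the frequency-weighted
#' sperm pool of the males and reports the daughter/son mass fractions
#' among live offspring.
#'
#' @param mother Genotype label or `xelim_genotype` (female).
#' @param males An `xelim_population` (its male classes are used) or a
#'   named numeric vector of male frequencies.
#' @param config Model configuration.
#' @return A list with `daughters`, `sons` (fractions of live offspring),
#'   `viable` (live fraction of zygote mass) and `offspring` (a tibble of
#'   adult classes).
#' @examples
#' cfg <- model_config()
#' pop <- ancestral_population(cfg)
#' brood_profile("XX EE SS RR gg", pop, cfg)
#' @export
brood_profile <- function(mother, males, config) {
  if (is.character(mother)) mother <- parse_genotype(mother, config)
  stopifnot(mother$sex == "female")
  m <- if (inherits(males, "xelim_population")) pop_vectors(males)$m
       else males
  m <- m / sum(m)
  eggs <- egg_classes(mother, config)
  sp <- pool_sperm(m, config)
  acc <- new.env(parent = emptyenv())
  sex_of <- new.env(parent = emptyenv())
  dead <- 0
  for (eg in eggs) {
    for (j in seq_along(sp$cls)) {
      w <- eg$p * sp$p[[j]]
      for (o in resolve_pair(eg, sp$cls[[j]], config)) {
        if (is.na(o$sex)) { dead <- dead + w * o$mass; next }
        acc[[o$label]] <- (if (is.null(acc[[o$label]])) 0
                           else acc[[o$label]]) + w * o$mass
        sex_of[[o$label]] <- o$sex
      }
    }
  }
  labs <- ls(acc)
  mass <- vapply(labs, function(l) acc[[l]], 0)
  sexes <- vapply(labs, function(l) sex_of[[l]], "")
  live <- sum(mass)
  off <- tibble::tibble(sex = sexes, genotype = labs, mass = unname(mass))
  off <- dplyr::arrange(off, .data$sex, dplyr::desc(.data$mass))
  list(
    daughters = if (live > 0) sum(mass[sexes == "female"]) / live else NA_real_,
    sons = if (live > 0) sum(mass[sexes == "male"]) / live else NA_real_,
    viable = live,
    offspring = off
  )
}

#' Classify a population state
#'
#' Labels the state `"monogenic"` (every female class with frequency above
#' `eps` produces a single-sex brood against the current male pool, and
#' both gynogenic and androgenic classes are present), `"digenic"` (no
#' single-sex female class), `"mixed"` (some but not the monogenic
#' pattern), or `"extinct"` (a sex absent).
#'
#' @param pop An `xelim_population`.
#' @param config Model configuration.
#' @param eps Presence threshold for a genotype class (default `1e-6`).
#' @param brood_tol Tolerance for calling a brood single-sex.
#' @return A list of class `xelim_classification` with elements `class` and
#'   `females` (per-class brood table: fraction of daughters and the
#'   gynogenic/androgenic/digenic call).
#' @examples
#' cfg <- model_config()
#' classify_population(ancestral_population(cfg), cfg)$class
#' @export
classify_population <- function(pop, config, eps = 1e-6, brood_tol = 1e-9) {
  v <- pop_vectors(pop)
  f <- v$f[v$f > eps]
  m <- v$m[v$m > eps]
  if (length(f) == 0L || length(m) == 0L) {
    return(structure(list(class = "extinct",
                          females = tibble::tibble()),
                     class = "xelim_classification"))
  }
  rows <- purrr::map(names(f), function(lab) {
    bp <- brood_profile(lab, m, config)
    type <- if (bp$viable <= brood_tol) "inviable"
      else if (bp$daughters >= 1 - brood_tol) "gynogenic"
      else if (bp$sons >= 1 - brood_tol) "androgenic"
      else "digenic"
    tibble::tibble(genotype = lab, frequency = unname(f[[lab]]),
                   frac_daughters = bp$daughters, type = type)
  })
  females <- dplyr::bind_rows(rows)
  fertile <- females[females$type != "inviable", , drop = FALSE]
  single <- fertile$type %in% c("gynogenic", "androgenic")
  cls <- if (nrow(fertile) == 0L) "extinct"
    else if (all(single) && all(c("gynogenic", "androgenic") %in%
                                fertile$type)) "monogenic"
    else if (!any(single)) "digenic"
    else "mixed"
  structure(list(class = cls, females = females),
            class = "xelim_classification")
}

#' @export
print.xelim_classification <- function(x, ...) {
  cat("<xelim_classification> ", x$class, "\n", sep = "")
  if (nrow(x$females)) print(x$females)
  invisible(x)
}

#' Single-pair cross table
#'
#' Expands one mother x father cross into its egg x sperm x fate table, in
#' the layout of the worked crosses: every egg class against every sperm
#' class, the zygote each pair forms, and the adult class (or death) it
#' resolves to.
#'
#' @param mother,father Genotype labels or `xelim_genotype` objects.
#' @param config Model configuration.
#' @return A tibble of class `xelim_cross` with columns `egg`, `cytoplasm`,
#'   `sperm`, `offspring`, `sex` and `mass` (masses sum to 1); the summary
#'   brood fractions ride along as attributes `daughters`/`sons`.
#' @examples
#' cfg <- model_config()
#' cross("XX ee ss rr gg", "g(X0 EE ss rr gg)", cfg)
#' @export
cross <- function(mother, father, config) {
  if (is.character(mother)) mother <- parse_genotype(mother, config)
  if (is.character(father)) father <- parse_genotype(father, config)
  stopifnot(mother$sex == "female", father$sex == "male")
  eggs <- egg_classes(mother, config)
  sps <- sperm_classes(father, config)
  rows <- list()
  for (eg in eggs) {
    cyto <- paste0(eg$de, "[e]",
                   if (eg$ds > 0) paste0(" + ", eg$ds, "[e*]"))
    egg_lab <- paste(c(if (config$e_linkage == "X") x_token_display(eg$x)
                       else "X", eg$al), collapse = " ")
    for (sp in sps) {
      sp_lab <- paste(c(if (sp$xn == 0L) "0"
                        else paste(rep(if (config$e_linkage == "X")
                          x_token_display(sp$x) else "X", sp$xn),
                          collapse = ""),
                        sp$al), collapse = " ")
      for (o in resolve_pair(eg, sp, config)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          egg = egg_lab, cytoplasm = cyto, sperm = sp_lab,
          offspring = o$label,
          sex = if (is.na(o$sex)) "dead" else o$sex,
          mass = eg$p * sp$p * o$mass
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$egg, .data$cytoplasm, .data$sperm,
                    .data$offspring, .data$sex) |>
    dplyr::summarise(mass = sum(.data$mass), .groups = "drop")
  live <- sum(out$mass[out$sex != "dead"])
  attr(out, "daughters") <- if (live > 0)
    sum(out$mass[out$sex == "female"]) / live else NA_real_
  attr(out, "sons") <- if (live > 0)
    sum(out$mass[out$sex == "male"]) / live else NA_real_
  class(out) <- c("xelim_cross", class(out))
  out
}
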