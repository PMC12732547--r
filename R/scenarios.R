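# Scenario definitions and the built-in emergence-sequence catalogue.
#
# A scenario is an initial population plus an ordered list of emergence
# stages; each stage introduces one derived allele at its introduction
# frequency, activates a per-stage viability regime (optionally carrying
# the previous stage's regime forward), and runs the recursion to
# equilibrium before the next gene appears.

#' Define one emergence stage
#'
#' @param locus Locus whose derived allele appears.
#' @param allele Allele introduced (default the lowercase derived allele).
#' @param freq Introduction frequency per allele copy (default 0.05, the
#'   protocol that leaves a monomorphic locus in Hardy-Weinberg proportions
#'   0.9025 / 0.095 / 0.0025).
#' @param selection `NULL` for a neutral emergence, or a
#'   [selection_regime()]; the string `"joint"` requests positive selection
#'   for the introduced allele with fitness dominance equal to the locus's
#'   configured functional dominance.
#' @param carry_forward Keep the previous stage's active regime in force
#'   alongside this stage's.
#' @param replace Resident allele replaced by the introduction (see
#'   [introduce_allele()]).
#' @param max_gens Optional per-stage generation cap.
#' @return A stage description list.
#' @export
stage <- function(locus, allele = locus, freq = 0.05, selection = NULL,
                  carry_forward = FALSE, replace = NULL, max_gens = NULL) {
  list(locus = locus, allele = allele, freq = freq, selection = selection,
       carry_forward = carry_forward, replace = replace, max_gens = max_gens)
}

#' Define a scenario
#'
#' @param name Scenario name.
#' @param config Model configuration.
#' @param initial Starting `xelim_population`.
#' @param stages List of [stage()] descriptions.
#' @return An object of class `xelim_scenario`.
#' @export
scenario <- function(name, config, initial, stages) {
  structure(list(name = name, config = config, initial = initial,
                 stages = stages),
            class = "xelim_scenario")
}

resolve_stage_selection <- function(st, config) {
  sel <- st$selection
  if (is.null(sel)) return(selection_regime())
  if (is.character(sel) && identical(sel, "none")) return(selection_regime())
  if (is.character(sel) && identical(sel, "joint")) {
    dom <- if (st$locus %in% names(config$dominance)) {
      config$dominance[[st$locus]]
    } else "recessive"
    return(selection_regime(st$locus, dom, mu = config$mu,
                            allele = st$allele))
  }
  if (is.list(sel) && !inherits(sel, "xelim_selection")) {
    return(selection_regime(st$locus,
                            dominance = sel$dominance %||% "recessive",
                            mu = sel$mu %||% config$mu,
                            allele = st$allele))
  }
  sel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_allele_fate <- function(traj, config, locus, allele, intro_freq,
                              eps_loss = 1e-6) {
  afs <- vapply(traj$states, function(st) {
    pop <- new_population(st$f, st$m, st$sr, st$gen)
    max(allele_frequency(pop, config, locus, allele)$frequency, na.rm = TRUE)
  }, 0)
  final <- afs[length(afs)]
  if (final >= 1 - eps_loss) return("fixed")
  if (final <= eps_loss) return("lost")
  # asymptotic elimination: monotone decay that will not cross the loss
  # threshold in finite time (e.g. a zygotic-lethal recessive decays
  # harmonically); called lost once it is far below its introduction level
  tailn <- min(length(afs) - 1L, 200L)
  if (tailn >= 4L) {
    recent <- utils::tail(afs, tailn + 1L)
    declining <- all(diff(recent) < 0)
    if (declining && final < min(1e-3, intro_freq / 2)) return("lost")
  }
  "polymorphic"
}

#' Run a scenario stage by stage
#'
#' Executes the stages in order: introduce the allele, run the recursion to
#' equilibrium under the stage's regime, classify the stable state and the
#' fate of the introduced allele (fixed, polymorphic, or lost — including
#' the asymptotic eliminations that decay towards zero without crossing the
#' loss threshold in finite time), then hand the state to the next stage.
#' Extinction ends the scenario as an outcome, not an error.
#'
#' Between stages, genotype classes whose frequency has fallen below
#' `prune` are removed and the state renormalised: each emergence starts
#' from the previous stable state proper, not from the numerical residue of
#' classes the previous stage eliminated asymptotically (an allele whose
#' carriers persist only at the 1e-20 level would otherwise be resurrected
#' by a later stage that reverses its selective sign).
#'
#' @param sc An [scenario()].
#' @param tol,max_gens,record_every Passed to [run_to_equilibrium()].
#' @param prune Between-stage class-presence threshold (default `1e-6`,
#'   the same threshold that makes allele loss decidable).
#' @return An `xelim_scenario_result` with per-stage results, the final
#'   state and the final outcome class.
#' @export
run_scenario <- function(sc, tol = 1e-10, max_gens = 20000L,
                         record_every = NULL, prune = 1e-6) {
  pop <- sc$initial
  config <- sc$config
  cumulative <- selection_regime()
  stage_results <- list()
  extinct <- NULL
  for (k in seq_along(sc$stages)) {
    st <- sc$stages[[k]]
    own <- resolve_stage_selection(st, config)
    # carry_forward keeps every earlier stage's own regime in force (a
    # gene's advantage read as a property of the gene, not of its stage)
    regime <- if (isTRUE(st$carry_forward)) bind_regimes(cumulative, own)
              else own
    pop <- introduce_allele(pop, config, st$locus, st$allele, st$freq,
                            replace = st$replace)
    traj <- run_to_equilibrium(pop, config, regime, tol = tol,
                               max_gens = st$max_gens %||% max_gens,
                               record_every = record_every)
    fate <- stage_allele_fate(traj, config, st$locus, st$allele, st$freq)
    pop <- if (is.null(traj$extinct)) prune_population(traj$final, prune)
           else traj$final
    cls <- if (!is.null(traj$extinct)) "extinct"
           else classify_population(pop, config)$class
    stage_results[[k]] <- list(
      locus = st$locus, allele = st$allele, regime = regime_sig(regime),
      generations = traj$generations, converged = traj$converged,
      extinct = traj$extinct, fate = fate, class = cls,
      sex_ratio = sex_ratio(pop), state = pop, trajectory = traj
    )
    cumulative <- bind_regimes(cumulative, own)
    if (!is.null(traj$extinct)) { extinct <- traj$extinct; break }
  }
  final_class <- stage_results[[length(stage_results)]]$class
  structure(list(scenario = sc, stages = stage_results,
                 final_state = pop, final_class = final_class,
                 extinct = extinct),
            class = "xelim_scenario_result")
}

#' @export
print.xelim_scenario_result <- function(x, ...) {
  cat("<xelim_scenario_result> ", x$scenario$name, ": ", x$final_class,
      "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Per-stage summary of a scenario result
#'
#' @param x An `xelim_scenario_result`.
#' @param ... Unused.
#' @return A tibble with one row per executed stage.
#' @exportS3Method generics::tidy
tidy.xelim_scenario_result <- function(x, ...) {
  purrr::map_dfr(seq_along(x$stages), function(k) {
    s <- x$stages[[k]]
    tibble::tibble(stage = k, locus = s$locus, allele = s$allele,
                   regime = s$regime, generations = s$generations,
                   converged = s$converged, fate = s$fate,
                   class = s$class, sex_ratio = s$sex_ratio)
  })
}

#' One-row scenario summary
#' @param x An `xelim_scenario_result`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::glance
glance.xelim_scenario_result <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario$name,
    stages_run = length(x$stages),
    outcome = x$final_class,
    monogenic = identical(x$final_class, "monogenic"),
    extinct = if (is.null(x$extinct)) NA_character_ else x$extinct
  )
}

#' The canonical monogenic population
#'
#' The stable monogenic composition: half gynogenic and half androgenic
#' females, the four ordered male genotypes at the maternal-inhibitor locus
#' at a quarter each, every male imprinted, sex ratio 1.  Under the
#' two-factor model the gynogenic female is the inhibitor homozygote
#' (two-dose eggs) and the androgenic female the heterozygote; under the
#' one-factor model the roles invert (the inhibitor itself eliminates, so
#' the zero-dose female is gynogenic).
#'
#' @param config Model configuration (autosomal `e`).
#' @return An `xelim_population`.
#' @export
monogenic_population <- function(config) {
  stopifnot(config$e_linkage == "autosomal")
  fixed <- function(sex, e_pair, imprinted = FALSE) {
    alleles <- list()
    for (l in config$loci) {
      alleles[[l]] <- switch(l, e = e_pair, s = c("s", "s"),
                             r = c("r", "r"), g = c("g", "g"),
                             c = c("c", "c"))
    }
    if (sex == "female") alleles <- canonical_female(alleles, config)
    format_genotype(new_genotype(sex, alleles, imprinted = imprinted), config)
  }
  fem <- if (config$variant == "two_factor") {
    c(fixed("female", c("E", "e")), fixed("female", c("e", "e")))
  } else {
    c(fixed("female", c("E", "E")), fixed("female", c("E", "e")))
  }
  mal <- c(fixed("male", c("E", "E"), TRUE), fixed("male", c("E", "e"), TRUE),
           fixed("male", c("e", "E"), TRUE), fixed("male", c("e", "e"), TRUE))
  new_population(stats::setNames(c(0.5, 0.5), fem),
                 stats::setNames(rep(0.25, 4), mal),
                 sex_ratio = 1, generation = 0L)
}

# ---- catalogue ------------------------------------------------------------

catalogue_path <- function() {
  system.file("extdata", "scenarios.yaml", package = "xelim",
              mustWork = TRUE)
}

#' Built-in scenario catalogue
#'
#' Reads the shipped structured-text catalogue and expands it into scenario
#' objects: the four imprinting-fixed dominance regimes crossed with all
#' six emergence orders of the inhibitor, spermatogenesis and elimination
#' genes; the non-imprinting grid; the imprinting-acquisition orders; the
#' enhanced-inhibitor follow-on; the one-factor pair; and the
#' carried-selection variant.
#'
#' @param path Catalogue file (default the shipped one).
#' @param groups Optional character vector restricting to catalogue groups.
#' @return Named list of `xelim_scenario` objects.
#' @export
scenario_catalogue <- function(path = catalogue_path(), groups = NULL) {
  cat_spec <- yaml::read_yaml(path)
  out <- list()
  for (grp in cat_spec$groups) {
    if (!is.null(groups) && !grp$group %in% groups) next
    config <- model_config(
      variant = grp$variant %||% "two_factor",
      loci = unlist(grp$loci),
      dominance = unlist(grp$dominance %||% list()),
      estar = isTRUE(grp$estar)
    )
    scen_defs <- grp$scenarios %||% list(list(name = grp$group))
    for (sd in scen_defs) {
      cfg <- config
      if (!is.null(sd$dominance)) {
        cfg <- model_config(
          variant = grp$variant %||% "two_factor",
          loci = unlist(grp$loci), dominance = unlist(sd$dominance),
          estar = isTRUE(grp$estar))
      }
      init <- if (identical(grp$initial, "monogenic")) {
        monogenic_population(cfg)
      } else {
        ancestral_population(cfg,
                             imprinting_fixed = isTRUE(grp$imprinting_fixed))
      }
      make_stages <- function(seq_str) {
        loci_seq <- strsplit(seq_str, "")[[1]]
        lapply(loci_seq, function(l) {
          d <- grp$stage_defaults[[l]] %||% list(selection = "none")
          stage(l, selection = d$selection %||% "none",
                freq = d$freq %||% 0.05,
                carry_forward = isTRUE(d$carry_forward))
        })
      }
      if (!is.null(grp$sequences)) {
        for (sq in unlist(grp$sequences)) {
          nm <- paste0(sd$name, "_", sq)
          out[[nm]] <- scenario(nm, cfg, init, make_stages(sq))
        }
      }
      if (!is.null(grp$stages)) {
        stages <- lapply(grp$stages, function(s) {
          stage(s$locus, allele = s$allele %||% s$locus,
                freq = s$freq %||% 0.05,
                selection = s$selection %||% "none",
                carry_forward = isTRUE(s$carry_forward),
                replace = s$replace)
        })
        out[[sd$name]] <- scenario(sd$name, cfg, init, stages)
      }
    }
  }
  out
}

#' Run a set of scenarios and tabulate the qualitative outcomes
#'
#' @param scenarios Named list of scenarios (default the full built-in
#'   catalogue).
#' @param tol,max_gens Passed to [run_scenario()].
#' @param record_every Trajectory thinning for the stage runs.
#' @return An `xelim_grid` (list of results); `tidy()` gives the outcome
#'   table.
#' @export
run_grid <- function(scenarios = scenario_catalogue(), tol = 1e-10,
                     max_gens = 20000L, record_every = 25L) {
  results <- lapply(scenarios, run_scenario, tol = tol, max_gens = max_gens,
                    record_every = record_every)
  structure(list(results = results), class = "xelim_grid")
}

#' Outcome table of a scenario grid
#'
#' @param x An `xelim_grid`.
#' @param ... Unused.
#' @return A tibble with one row per scenario: outcome class, monogenic
#'   flag, the per-stage allele fates, and the extinction reason if any.
#' @exportS3Method generics::tidy
tidy.xelim_grid <- function(x, ...) {
  purrr::map_dfr(names(x$results), function(nm) {
    res <- x$results[[nm]]
    fates <- vapply(res$stages, function(s) {
      paste0(s$locus, ":", s$fate)
    }, "")
    tibble::tibble(
      scenario = nm,
      outcome = res$final_class,
      monogenic = identical(res$final_class, "monogenic"),
      stages = paste(fates, collapse = " "),
      extinct = if (is.null(res$extinct)) NA_character_ else res$extinct
    )
  })
}

#' @export
print.xelim_grid <- function(x, ...) {
  cat("<xelim_grid> ", length(x$results), " scenarios\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}
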