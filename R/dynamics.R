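# The generation recursion over an infinite panmictic population.
#
# Discrete non-overlapping generations, no migration, mating-neutral loci,
# equal female fecundity and non-limiting male fertilisation.  Random mating
# then factorises the zygote distribution into (pooled egg classes) x
# (pooled sperm classes); each distinct egg x sperm pair resolves through
# the elimination engine (memoised), viability selection multiplies the
# surviving adults of both sexes, the sex ratio is recorded, and each sex
# renormalises to 1.  Everything is deterministic: "random" elimination
# targets are mass splits, so runs are bit-reproducible.

# per-label gamete distributions with precomputed class keys, memoised so
# the per-generation pooling never re-derives or re-formats anything
gametes_for <- function(lab, sex, config) {
  env <- cache_env("gametes")
  key <- paste0(config$sig, "\r", sex, "\r", lab)
  hit <- env[[key]]
  if (!is.null(hit)) return(hit)
  cls <- if (sex == "female") egg_classes(parsed(lab, config), config)
         else sperm_classes(parsed(lab, config), config)
  keys <- vapply(cls, if (sex == "female") egg_key else sperm_key, "")
  out <- list(keys = keys, p = vapply(cls, function(g) g$p, 0), cls = cls)
  env[[key]] <- out
  out
}

pool_gametes <- function(vec, sex, config) {
  labs <- names(vec)
  gs <- lapply(labs, gametes_for, sex = sex, config = config)
  keys <- unlist(lapply(gs, function(g) g$keys), use.names = FALSE)
  w <- unlist(lapply(seq_along(gs), function(i) gs[[i]]$p * vec[[i]]),
              use.names = FALSE)
  p <- rowsum(w, keys)  # sorted by key
  reg <- new.env(parent = emptyenv())
  for (g in gs) {
    for (i in seq_along(g$keys)) {
      if (is.null(reg[[g$keys[i]]])) reg[[g$keys[i]]] <- g$cls[[i]]
    }
  }
  ukeys <- rownames(p)
  list(p = stats::setNames(as.vector(p), ukeys),
       cls = lapply(ukeys, function(k) reg[[k]]))
}

pool_eggs <- function(f, config) pool_gametes(f, "female", config)

pool_sperm <- function(m, config) pool_gametes(m, "male", config)

# cached bilinear structure: for a fixed set of egg and sperm classes, the
# flattened (combo -> outcome) map used to vectorise the generation step
offspring_structure <- function(egg_keys, sperm_keys, eggs, sperm, config) {
  key <- paste0(config$sig, "\r", paste(egg_keys, collapse = ";"), "\r",
                paste(sperm_keys, collapse = ";"))
  env <- cache_env("structure")
  hit <- env[[key]]
  if (!is.null(hit)) return(hit)
  ci <- integer(0); cj <- integer(0); lab <- character(0)
  sx <- character(0); fr <- numeric(0)
  for (i in seq_along(eggs)) {
    for (j in seq_along(sperm)) {
      for (o in resolve_pair(eggs[[i]], sperm[[j]], config)) {
        if (is.na(o$sex)) next # dead mass is simply lost
        ci <- c(ci, i); cj <- c(cj, j)
        lab <- c(lab, o$label); sx <- c(sx, o$sex); fr <- c(fr, o$mass)
      }
    }
  }
  ulab <- unique(lab)
  st <- list(ci = ci, cj = cj, fr = fr,
             lab_id = match(lab, ulab), labels = ulab,
             female = sx == "female")
  env[[key]] <- st
  st
}

# full one-generation transition structure for fixed per-sex label sets:
# gamete-pooling matrices plus the flattened (egg x sperm -> adult) map,
# with the per-label viability folded in; cached so that a converging run
# reduces to two small matrix products and a rowsum per generation
step_structure <- function(flabs, mlabs, config, selection) {
  skey <- paste(config$sig, regime_sig(selection),
                paste(flabs, collapse = ";"), paste(mlabs, collapse = ";"),
                sep = "\r")
  env <- cache_env("step")
  hit <- env[[skey]]
  if (!is.null(hit)) return(hit)
  ep <- pool_gametes(stats::setNames(rep(1, length(flabs)), flabs),
                     "female", config)
  sp <- pool_gametes(stats::setNames(rep(1, length(mlabs)), mlabs),
                     "male", config)
  Ef <- matrix(0, length(ep$p), length(flabs),
               dimnames = list(names(ep$p), flabs))
  for (lab in flabs) {
    g <- gametes_for(lab, "female", config)
    Ef[g$keys, lab] <- Ef[g$keys, lab] + g$p
  }
  Sm <- matrix(0, length(sp$p), length(mlabs),
               dimnames = list(names(sp$p), mlabs))
  for (lab in mlabs) {
    g <- gametes_for(lab, "male", config)
    Sm[g$keys, lab] <- Sm[g$keys, lab] + g$p
  }
  st <- offspring_structure(names(ep$p), names(sp$p), ep$cls, sp$cls, config)
  st$Ef <- Ef
  st$Sm <- Sm
  st$w <- fitness_vector(st$labels, config, selection)
  st$fid <- st$lab_id[st$female]
  st$mid <- st$lab_id[!st$female]
  env[[skey]] <- st
  st
}

step_vectors <- function(v, config, selection = NULL) {
  st <- step_structure(names(v$f), names(v$m), config, selection)
  ep <- list(p = drop(st$Ef %*% v$f))
  sp <- list(p = drop(st$Sm %*% v$m))
  mass <- ep$p[st$ci] * sp$p[st$cj] * st$fr
  # viability selection on adults of both sexes
  mass <- mass * st$w[st$lab_id]
  fem <- st$female
  f2 <- rowsum(mass[fem], st$lab_id[fem])
  m2 <- rowsum(mass[!fem], st$lab_id[!fem])
  fv <- stats::setNames(as.vector(f2), st$labels[as.integer(rownames(f2))])
  mv <- stats::setNames(as.vector(m2), st$labels[as.integer(rownames(m2))])
  fv <- fv[fv > 1e-300]
  mv <- mv[mv > 1e-300]
  fm <- sum(fv); mm <- sum(mv)
  if (fm <= 0 || mm <= 0) {
    cond <- structure(
      class = c("xelim_extinct", "error", "condition"),
      list(message = paste0("population extinct: no ",
                            if (mm <= 0) "males" else "females"),
           call = NULL,
           missing_sex = if (mm <= 0) "male" else "female"))
    stop(cond)
  }
  list(f = fv / fm, m = mv / mm, sr = mm / fm)
}

fitness_vector <- function(labels, config, selection) {
  if (is.null(selection) || nrow(selection) == 0L) {
    return(rep(1, length(labels)))
  }
  env <- cache_env("fitness")
  sig <- paste0(config$sig, "\r", regime_sig(selection), "\r")
  vapply(labels, function(lab) {
    k <- paste0(sig, lab)
    hit <- env[[k]]
    if (!is.null(hit)) return(hit)
    w <- fitness_w(parsed(lab, config), selection, config)
    env[[k]] <- w
    w
  }, 0)
}

#' Advance a population by one generation
#'
#' Accumulates the zygote mass of every (mother, father, egg, sperm)
#' combination under random mating, resolves each zygote through the
#' elimination engine, applies viability selection to the surviving adults
#' of both sexes, records the sex ratio, and renormalises each sex.
#'
#' @param pop An `xelim_population`.
#' @param config Model configuration.
#' @param selection A [selection_regime()] or `NULL` for neutrality.
#' @return The next `xelim_population`.  Signals a classed condition
#'   (`xelim_extinct`) if either sex's offspring mass is exactly zero.
#' @export
next_generation <- function(pop, config, selection = NULL) {
  v <- pop_vectors(pop)
  nx <- step_vectors(v, config, selection)
  new_population(nx$f, nx$m, sex_ratio = nx$sr,
                 generation = attr(pop, "generation") + 1L)
}

#' Iterate the recursion to an equilibrium
#'
#' Runs [next_generation()] until the largest absolute change of any
#' per-sex genotype frequency falls below `tol`, the generation cap is
#' reached, or the population goes extinct (either sex's mass vanishing, or
#' the sex ratio passing `sr_extinct` or its reciprocal — the deterministic
#' signature of a sex being lost asymptotically).
#'
#' @param pop Starting `xelim_population`.
#' @param config Model configuration.
#' @param selection A [selection_regime()] or `NULL`.
#' @param tol Convergence tolerance on the L-infinity change (default
#'   `1e-10`).
#' @param max_gens Generation cap (default 20000); reaching it reports
#'   non-convergence, it is not an error.
#' @param sr_extinct Sex-ratio threshold declaring a sex effectively lost.
#' @param record_every Keep every k-th state in the trajectory (default:
#'   every state up to 2000 generations, thinned beyond).  The final state
#'   is always kept.
#' @return An `xelim_trajectory`: recorded states, the final state, the
#'   generation count, convergence flag, final delta, and the extinction
#'   reason (`NULL` if none).
#' @examples
#' cfg <- model_config()
#' pop <- ancestral_population(cfg) |>
#'   introduce_allele(cfg, "s", freq = 0.05)
#' run_to_equilibrium(pop, cfg, selection_regime("s", "recessive"),
#'                    tol = 1e-6)
#' @export
run_to_equilibrium <- function(pop, config, selection = NULL, tol = 1e-10,
                               max_gens = 20000L, sr_extinct = 1e-6,
                               record_every = NULL) {
  stopifnot(tol > 0)
  if (is.null(record_every)) {
    record_every <- max(1L, as.integer(ceiling(max_gens / 2000)))
  }
  v <- pop_vectors(pop)
  gen0 <- attr(pop, "generation")
  states <- list(list(f = v$f, m = v$m, sr = attr(pop, "sex_ratio"),
                      gen = gen0))
  delta <- Inf
  converged <- FALSE
  extinct <- NULL
  sr <- attr(pop, "sex_ratio")
  g <- 0L
  while (g < max_gens) {
    nx <- tryCatch(step_vectors(v, config, selection),
                   xelim_extinct = function(e) e)
    if (inherits(nx, "xelim_extinct")) {
      extinct <- nx$missing_sex
      break
    }
    g <- g + 1L
    delta <- linf_delta(v, nx)
    v <- list(f = nx$f, m = nx$m)
    sr <- nx$sr
    if (g %% record_every == 0L) {
      states[[length(states) + 1L]] <-
        list(f = v$f, m = v$m, sr = sr, gen = gen0 + g)
    }
    if (delta < tol) { converged <- TRUE; break }
    if (sr < sr_extinct) { extinct <- "male"; break }
    if (sr > 1 / sr_extinct) { extinct <- "female"; break }
  }
  last <- states[[length(states)]]
  if (last$gen != gen0 + g) {
    states[[length(states) + 1L]] <-
      list(f = v$f, m = v$m, sr = sr, gen = gen0 + g)
  }
  structure(list(
    states = states,
    final = new_population(v$f, v$m, sex_ratio = sr, generation = gen0 + g),
    generations = g,
    converged = converged,
    delta = delta,
    extinct = extinct,
    config = config,
    selection = selection
  ), class = "xelim_trajectory")
}

linf_delta <- function(a, b) {
  d <- 0
  for (sx in c("f", "m")) {
    labs <- union(names(a[[sx]]), names(b[[sx]]))
    av <- stats::setNames(numeric(length(labs)), labs)
    bv <- av
    av[names(a[[sx]])] <- a[[sx]]
    bv[names(b[[sx]])] <- b[[sx]]
    d <- max(d, max(abs(av - bv)))
  }
  d
}

#' @export
print.xelim_trajectory <- function(x, ...) {
  cat("<xelim_trajectory> ", x$generations, " generations; ",
      if (!is.null(x$extinct)) paste0("EXTINCT (no ", x$extinct, "s)")
      else if (x$converged) paste0("converged (delta ",
                                   format(x$delta, digits = 3), ")")
      else "not converged", "\n", sep = "")
  cat("final state:\n")
  print(x$final)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into a long frequency table
#'
#' @param x An `xelim_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `generation`, `sex`, `genotype`,
#'   `frequency`, `sex_ratio` (one row per recorded state and class).
#' @exportS3Method generics::tidy
tidy.xelim_trajectory <- function(x, ...) {
  purrr::map_dfr(x$states, function(st) {
    tibble::tibble(
      generation = st$gen,
      sex = c(rep("female", length(st$f)), rep("male", length(st$m))),
      genotype = c(names(st$f), names(st$m)),
      frequency = c(unname(st$f), unname(st$m)),
      sex_ratio = st$sr
    )
  })
}

#' One-row summary of a trajectory
#'
#' @param x An `xelim_trajectory`.
#' @param ... Unused.
#' @return A tibble with the generation count, convergence flag, final
#'   L-infinity delta, final sex ratio, class counts and extinction reason.
#' @exportS3Method generics::glance
glance.xelim_trajectory <- function(x, ...) {
  v <- pop_vectors(x$final)
  tibble::tibble(
    generations = x$generations,
    converged = x$converged,
    delta = x$delta,
    sex_ratio = sex_ratio(x$final),
    n_female_classes = length(v$f),
    n_male_classes = length(v$m),
    extinct = if (is.null(x$extinct)) NA_character_ else x$extinct
  )
}

#' Trajectory plot
#'
#' Genotype frequencies over generations, one panel per sex, with the sex
#' ratio as a dashed overlay in its own panel.
#'
#' @param object An `xelim_trajectory`.
#' @param min_frequency Classes whose frequency never exceeds this are
#'   dropped from the plot for legibility.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.xelim_trajectory <- function(object, min_frequency = 1e-3, ...) {
  td <- tidy(object)
  keep <- td |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(mx = max(.data$frequency), .groups = "drop") |>
    dplyr::filter(.data$mx >= min_frequency)
  td <- dplyr::semi_join(td, keep, by = "genotype")
  ggplot2::ggplot(td, ggplot2::aes(.data$generation, .data$frequency,
                                   colour = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~sex, ncol = 1) +
    ggplot2::labs(x = "generation", y = "frequency within sex",
                  colour = "genotype") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
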