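# Gametogenesis: the gamete algebra of the model.
#
# Oogenesis is conventional (Mendelian, loci unlinked), with two maternal
# effects attached to every egg of a female: the cytoplasmic dose of the
# maternal inhibitor ([e]/[e*]) equal to the mother's allele count, and the
# imprint mark set when the mother is functionally imprinting.  AB
# spermatogenesis (functional s) makes the maternally and paternally derived
# complements segregate intact: an imprinted father transmits only the
# maternal complement; an unimprinted one transmits each complement with
# probability 1/2 and never a recombinant.

# internal egg class: list(x = token, al = named chr (autosomal alleles),
#                          de, ds, mark, p)
egg_key <- function(eg) {
  paste(eg$x, paste(eg$al, collapse = ""), eg$de, eg$ds, eg$mark, sep = "|")
}

# internal sperm class: list(xn = 0/1/2, x = token or NA, al, p)
sperm_key <- function(sp) {
  paste(sp$xn, if (is.na(sp$x)) "-" else sp$x,
        paste(sp$al, collapse = ""), sep = "|")
}

mother_doses <- function(ind, config) {
  if (!"e" %in% config$loci) return(c(de = 0L, ds = 0L))
  a <- base_allele(ind$alleles[["e"]])
  a <- a[!is.na(a)]
  c(de = sum(a == "e"), ds = sum(a == "e*"))
}

mother_imprints <- function(ind, config) {
  if (!"g" %in% config$loci) return(FALSE)
  is_functional(ind$alleles[["g"]], config$dominance[["g"]], "g")
}

egg_classes <- function(ind, config) {
  key <- paste0(config$sig, "\r", genotype_label(ind, config))
  env <- cache_env("eggs")
  hit <- env[[key]]
  if (!is.null(hit)) return(hit)
  stopifnot(ind$sex == "female")
  d <- mother_doses(ind, config)
  mark <- mother_imprints(ind, config)
  xl <- config$e_linkage == "X"
  x_opts <- if (xl) ind$alleles[["e"]] else "X"
  al <- aut_loci(config)
  opt_list <- c(list(x = unique(x_opts)),
                stats::setNames(lapply(al, function(l) {
                  unique(ind$alleles[[l]])
                }), al))
  p_list <- lapply(names(opt_list), function(nm) {
    opts <- opt_list[[nm]]
    src <- if (nm == "x") x_opts else ind$alleles[[nm]]
    vapply(opts, function(o) mean(src == o), 0)
  })
  grid <- expand.grid(opt_list, stringsAsFactors = FALSE)
  pgrid <- expand.grid(p_list)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    list(x = grid$x[i],
         al = stats::setNames(as.character(grid[i, al, drop = TRUE]), al),
         de = unname(d["de"]), ds = unname(d["ds"]), mark = mark,
         p = prod(as.numeric(pgrid[i, ])))
  })
  env[[key]] <- out
  out
}

sperm_classes <- function(ind, config) {
  key <- paste0(config$sig, "\r", genotype_label(ind, config))
  env <- cache_env("sperm")
  hit <- env[[key]]
  if (!is.null(hit)) return(hit)
  stopifnot(ind$sex == "male")
  al <- aut_loci(config)
  s_fun <- "s" %in% config$loci &&
    is_functional(ind$alleles[["s"]], config$dominance[["s"]], "s")
  c_fun <- "c" %in% config$loci &&
    is_functional(ind$alleles[["c"]], config$dominance[["c"]], "c")
  xl <- config$e_linkage == "X"
  own_x <- if (xl) ind$alleles[["e"]][!is.na(ind$alleles[["e"]])][1] else "X"
  xn_bearing <- if (c_fun) 2L else 1L

  complement <- function(side) {
    i <- if (side == "maternal") 1L else 2L
    als <- stats::setNames(
      vapply(al, function(l) ind$alleles[[l]][i], ""), al)
    has_x <- ind$x_origin == side
    list(xn = if (has_x) xn_bearing else 0L,
         x = if (has_x) own_x else NA_character_, al = als, p = 0.5)
  }

  if (s_fun && ind$imprinted) {
    cls <- complement("maternal")
    cls$p <- 1
    out <- list(cls)
  } else if (s_fun) {
    out <- list(complement("maternal"), complement("paternal"))
  } else {
    # Mendelian: X vs no-X each 1/2, independent of every autosomal locus
    opt_list <- stats::setNames(lapply(al, function(l) {
      unique(ind$alleles[[l]])
    }), al)
    p_list <- lapply(al, function(l) {
      opts <- unique(ind$alleles[[l]])
      vapply(opts, function(o) mean(ind$alleles[[l]] == o), 0)
    })
    grid <- expand.grid(opt_list, stringsAsFactors = FALSE)
    pgrid <- expand.grid(p_list)
    out <- list()
    for (i in seq_len(nrow(grid))) {
      als <- stats::setNames(as.character(grid[i, al, drop = TRUE]), al)
      p_a <- prod(as.numeric(pgrid[i, ]))
      out <- c(out,
               list(list(xn = xn_bearing, x = own_x, al = als, p = p_a / 2),
                    list(xn = 0L, x = NA_character_, al = als, p = p_a / 2)))
    }
  }
  # collapse identical classes
  keys <- vapply(out, sperm_key, "")
  if (anyDuplicated(keys)) {
    out <- lapply(split(out, keys), function(grp) {
      cls <- grp[[1]]
      cls$p <- sum(vapply(grp, function(g) g$p, 0))
      cls
    })
    out <- unname(out)
  }
  env[[key]] <- out
  out
}

gamete_tibble_eggs <- function(classes, config) {
  tibble::tibble(
    x = vapply(classes, function(e) e$x, ""),
    haplotype = vapply(classes, function(e) paste(e$al, collapse = " "), ""),
    cytoplasm_e = vapply(classes, function(e) as.integer(e$de), 1L),
    cytoplasm_estar = vapply(classes, function(e) as.integer(e$ds), 1L),
    imprint_mark = vapply(classes, function(e) e$mark, TRUE),
    probability = vapply(classes, function(e) e$p, 0)
  )
}

gamete_tibble_sperm <- function(classes, config) {
  tibble::tibble(
    x_content = vapply(classes, function(s) as.integer(s$xn), 1L),
    x = vapply(classes, function(s) s$x, ""),
    haplotype = vapply(classes, function(s) paste(s$al, collapse = " "), ""),
    probability = vapply(classes, function(s) s$p, 0)
  )
}

#' Egg classes of a female
#'
#' Enumerates the egg classes a female produces: Mendelian segregation over
#' unlinked loci, one X per egg (X-linked alleles travel with their X), a
#' cytoplasmic inhibitor dose equal to the mother's allele count at the
#' maternal-effect locus (identical in every egg class of one female), and
#' the imprint mark when the mother is functionally imprinting.
#'
#' @param mother An `xelim_genotype` or a genotype label.
#' @param config Model configuration.
#' @return A tibble with one row per egg class; `probability` sums to 1.
#' @examples
#' cfg <- model_config()
#' oogenesis("XX Ee ss rr gg", cfg)
#' @export
oogenesis <- function(mother, config) {
  if (is.character(mother)) mother <- parse_genotype(mother, config)
  if (mother$sex != "female") {
    stop("oogenesis requires a female genotype", call. = FALSE)
  }
  gamete_tibble_eggs(egg_classes(mother, config), config)
}

#' Sperm classes of a male
#'
#' Three regimes.  When the spermatogenesis modifier is not functional,
#' segregation is Mendelian with X- and 0-bearing sperm at 1/2 each,
#' independent of every autosomal locus.  When it is functional and the
#' father was imprinted, all sperm carry his intact maternally derived
#' complement (meiotic drive: X-bearing sperm only, for a maternally derived
#' X).  When functional without imprinting, the maternal and paternal
#' complements are transmitted at 1/2 each with no recombinants.  Under the
#' sciarid chromatid-nondisjunction gene, X-bearing sperm carry two
#' identical copies of the X.
#'
#' @param father An `xelim_genotype` or genotype label.
#' @param config Model configuration.
#' @return A tibble with one row per sperm class; `probability` sums to 1.
#' @examples
#' cfg <- model_config()
#' spermatogenesis("g(X0 eE ss rr gg)", cfg)
#' @export
spermatogenesis <- function(father, config) {
  if (is.character(father)) father <- parse_genotype(father, config)
  if (father$sex != "male") {
    stop("spermatogenesis requires a male genotype", call. = FALSE)
  }
  gamete_tibble_sperm(sperm_classes(father, config), config)
}
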