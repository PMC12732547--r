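# Parent-of-origin-resolved genotypes and their canonical text labels.
#
# A genotype stores, per locus, the ordered (maternal, paternal) allele pair.
# Males additionally record whether their mother imprinted them (the g(...)
# prefix of the label) and which parent contributed their retained X.  Female
# heterozygote order is phenotypically inert (oogenesis is Mendelian), so
# female pairs are canonicalised to allele-rank order and the two orders are
# aggregated under one label.

.xelim_cache <- new.env(parent = emptyenv())

cache_env <- function(name) {
  if (is.null(.xelim_cache[[name]])) {
    .xelim_cache[[name]] <- new.env(parent = emptyenv())
  }
  .xelim_cache[[name]]
}

#' Clear the package memoisation caches
#'
#' Gamete distributions, zygote resolutions and parsed labels are memoised
#' per configuration.  The caches are keyed by the configuration signature so
#' clearing is never required for correctness; this is an aid for memory
#' profiling.
#' @return Invisibly `NULL`.
#' @export
xelim_clear_cache <- function() {
  rm(list = ls(.xelim_cache), envir = .xelim_cache)
  invisible(NULL)
}

new_genotype <- function(sex, alleles, imprinted = FALSE,
                         x_origin = "maternal") {
  structure(list(sex = sex, alleles = alleles, imprinted = imprinted,
                 x_origin = x_origin),
            class = "xelim_genotype")
}

allele_rank <- function(a, locus, config) {
  match(a, config$alleles[[locus]])
}

# canonical female: each pair sorted by allele rank (ancestral first); for
# an X-linked e locus the inhibitor-carrying chromosome prints first, which
# matches the conventional ordering of the sciarid female formulae
canonical_female <- function(alleles, config) {
  for (l in names(alleles)) {
    pr <- alleles[[l]]
    if (!anyNA(pr) && length(pr) == 2L) {
      r <- allele_rank(pr, l, config)
      if (l == "e" && config$e_linkage == "X") {
        r <- r + ifelse(base_allele(pr) == "e", 0L, 100L)
      }
      alleles[[l]] <- pr[order(r)]
    }
  }
  alleles
}

#' Construct an individual genotype
#'
#' @param sex `"female"` or `"male"`.
#' @param ... Named per-locus allele pairs, maternal allele first, e.g.
#'   `e = c("E", "e")`.  A single allele is taken as homozygous (or, for the
#'   X-linked locus of a male, hemizygous).
#' @param imprinted For males: whether the mother performed imprinting.
#' @param x_origin For males: which parent contributed the retained X.
#' @param config Model configuration.
#' @return An `xelim_genotype`.
#' @examples
#' cfg <- model_config()
#' genotype("female", e = c("E", "e"), s = "s", r = "r", g = "g",
#'          config = cfg)
#' @export
genotype <- function(sex, ..., imprinted = FALSE, x_origin = "maternal",
                     config) {
  prs <- list(...)
  alleles <- list()
  for (l in config$loci) {
    pr <- prs[[l]]
    if (is.null(pr)) stop("missing allele pair for locus ", l, call. = FALSE)
    if (length(pr) == 1L) {
      pr <- if (sex == "male" && l == "e" && config$e_linkage == "X") {
        if (x_origin == "maternal") c(pr, NA) else c(NA, pr)
      } else c(pr, pr)
    }
    ok <- stats::na.omit(pr) %in% config$alleles[[l]]
    if (!all(ok)) stop("unknown allele at locus ", l, call. = FALSE)
    alleles[[l]] <- pr
  }
  if (sex == "female") {
    alleles <- canonical_female(alleles, config)
    imprinted <- FALSE
    x_origin <- "maternal"
  }
  new_genotype(sex, alleles, imprinted, x_origin)
}

# ---- labels ---------------------------------------------------------------

x_token_display <- function(a) {
  b <- base_allele(a)
  inv <- grepl("\\|Inv$", a)
  paste0(if (inv) "Inv", if (b == "e") "Xe" else "X")
}

#' Format a genotype in the standard cross notation
#'
#' Females print as `XX Ee ss rr gg` (allele pairs in configuration locus
#' order, heterozygote order aggregated with the ancestral allele first).
#' Males print the maternal allele first at every locus and are wrapped
#' `g(...)` when their mother imprinted them; `X0` marks a maternally derived
#' retained X and `0X` a paternally derived one.  With X-linked `e` the X
#' part spells out the chromosome tokens, e.g. `InvXeX cc ss rr gg`.
#'
#' @param ind An `xelim_genotype`.
#' @param config Model configuration.
#' @return A single character label; [parse_genotype()] is its inverse.
#' @export
format_genotype <- function(ind, config) {
  xl <- config$e_linkage == "X"
  parts <- character(0)
  if (ind$sex == "female") {
    xpart <- if (xl) {
      pr <- ind$alleles[["e"]]
      paste0(x_token_display(pr[1]), x_token_display(pr[2]))
    } else "XX"
  } else {
    xtok <- if (xl) {
      pr <- ind$alleles[["e"]]
      x_token_display(pr[!is.na(pr)][1])
    } else "X"
    xpart <- if (ind$x_origin == "maternal") paste0(xtok, "0")
             else paste0("0", xtok)
  }
  parts <- xpart
  for (l in aut_loci(config)) {
    parts <- c(parts, paste0(ind$alleles[[l]], collapse = ""))
  }
  lab <- paste(parts, collapse = " ")
  if (ind$sex == "male" && ind$imprinted) lab <- paste0("g(", lab, ")")
  lab
}

split_allele_pair <- function(txt, locus, config) {
  symbols <- config$alleles[[locus]]
  symbols <- symbols[order(-nchar(symbols))]
  out <- character(0)
  rest <- txt
  while (nchar(rest) > 0L) {
    hit <- NA_character_
    for (s in symbols) {
      if (startsWith(rest, s)) { hit <- s; break }
    }
    if (is.na(hit)) stop("cannot parse allele pair '", txt, "' at locus ",
                         locus, call. = FALSE)
    out <- c(out, hit)
    rest <- substring(rest, nchar(hit) + 1L)
  }
  if (length(out) != 2L) stop("allele pair '", txt, "' at locus ", locus,
                              " does not have two alleles", call. = FALSE)
  out
}

split_x_part <- function(txt, config) {
  # returns list(tokens = character of X tokens in printed order,
  #              zero_pos = position of "0" among printed symbols or NA)
  if (config$e_linkage != "X") {
    displays <- c("X", "0")
    token_of <- c(X = "X")
  } else {
    toks <- config$alleles[["e"]]
    displays <- c(vapply(toks, x_token_display, ""), "0")
    token_of <- stats::setNames(toks, vapply(toks, x_token_display, ""))
  }
  displays <- unique(displays[order(-nchar(displays))])
  out <- character(0)
  rest <- txt
  while (nchar(rest) > 0L) {
    hit <- NA_character_
    for (s in displays) if (startsWith(rest, s)) { hit <- s; break }
    if (is.na(hit)) stop("cannot parse X part '", txt, "'", call. = FALSE)
    out <- c(out, hit)
    rest <- substring(rest, nchar(hit) + 1L)
  }
  zero_pos <- which(out == "0")
  tokens <- out[out != "0"]
  tokens <- unname(if (config$e_linkage == "X") token_of[tokens]
                   else rep("X", length(tokens)))
  list(tokens = tokens,
       zero_pos = if (length(zero_pos)) zero_pos[1] else NA_integer_)
}

#' Parse a genotype label
#'
#' @param label Canonical label as produced by [format_genotype()].
#' @param config Model configuration.
#' @return An `xelim_genotype`.
#' @export
parse_genotype <- function(label, config) {
  key <- paste0(config$sig, "\r", label)
  env <- cache_env("parse")
  hit <- env[[key]]
  if (!is.null(hit)) return(hit)

  raw <- label
  imprinted <- FALSE
  if (grepl("^g\\(.*\\)$", raw)) {
    imprinted <- TRUE
    raw <- sub("^g\\((.*)\\)$", "\\1", raw)
  }
  parts <- strsplit(trimws(raw), "\\s+")[[1]]
  xp <- split_x_part(parts[1], config)
  n_x <- length(xp$tokens)
  sex <- if (is.na(xp$zero_pos)) "female" else "male"
  if (sex == "female" && n_x != 2L) {
    stop("female label must carry two X chromosomes: ", label, call. = FALSE)
  }
  if (sex == "male" && n_x != 1L) {
    stop("male label must carry one X chromosome: ", label, call. = FALSE)
  }
  x_origin <- if (sex == "male" && xp$zero_pos == 1L) "paternal" else "maternal"
  al <- aut_loci(config)
  if (length(parts) != 1L + length(al)) {
    stop("label '", label, "' does not match the configured loci",
         call. = FALSE)
  }
  alleles <- list()
  if (config$e_linkage == "X") {
    alleles[["e"]] <- if (sex == "female") xp$tokens
      else if (x_origin == "maternal") c(xp$tokens, NA) else c(NA, xp$tokens)
  }
  for (i in seq_along(al)) {
    alleles[[al[i]]] <- split_allele_pair(parts[i + 1L], al[i], config)
  }
  alleles <- alleles[config$loci[config$loci %in% names(alleles)]]
  if (sex == "female") alleles <- canonical_female(alleles, config)
  ind <- new_genotype(sex, alleles, imprinted && sex == "male", x_origin)
  env[[key]] <- ind
  ind
}

genotype_label <- function(ind, config) format_genotype(ind, config)

# memoised label -> parsed genotype
parsed <- function(label, config) parse_genotype(label, config)

#' @export
print.xelim_genotype <- function(x, ...) {
  cat("<xelim_genotype> ", x$sex, "\n", sep = "")
  utils::str(x$alleles, give.attr = FALSE)
  invisible(x)
}

#' Enumerate every genotype label of a configuration
#'
#' Enumerates the full per-sex genotype space: all ordered allele pairs for
#' males (crossed with the imprinting flag) and all unordered pairs for
#' females.  Used by the round-trip and brute-force property tests; the
#' spaces are small (a few hundred labels for four loci).
#'
#' @param config Model configuration.
#' @param sex `"female"` or `"male"`.
#' @param imprinted For males, which imprinting states to include.
#' @return Character vector of canonical labels.
#' @export
enumerate_genotypes <- function(config, sex = c("female", "male"),
                                imprinted = c(TRUE, FALSE)) {
  sex <- match.arg(sex)
  combos <- list()
  for (l in config$loci) {
    a <- config$alleles[[l]]
    if (sex == "male" && l == "e" && config$e_linkage == "X") {
      combos[[l]] <- lapply(a, function(x) c(x, NA))
    } else {
      prs <- expand.grid(m = a, p = a, stringsAsFactors = FALSE)
      combos[[l]] <- lapply(seq_len(nrow(prs)),
                            function(i) c(prs$m[i], prs$p[i]))
    }
  }
  idx <- expand.grid(lapply(combos, seq_along))
  labs <- character(0)
  for (i in seq_len(nrow(idx))) {
    alleles <- list()
    for (l in config$loci) alleles[[l]] <- combos[[l]][[idx[i, l]]]
    if (sex == "female") {
      labs <- c(labs, format_genotype(
        new_genotype("female", canonical_female(alleles, config)), config))
    } else {
      for (im in imprinted) {
        labs <- c(labs, format_genotype(
          new_genotype("male", alleles, imprinted = im), config))
      }
    }
  }
  unique(labs)
}
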