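# Population states: per-sex genotype-frequency tables.
#
# The user-facing container is a tibble (sex, genotype, frequency) so states
# pipe through dplyr naturally; the recursion works on named numeric vectors
# internally.  Frequencies are normalised within each sex; the sex ratio
# (male mass / female mass of the adult cohort, recorded after viability
# selection and before the per-sex renormalisation) and the generation
# counter ride along as attributes.

new_population <- function(f, m, sex_ratio = NA_real_, generation = 0L) {
  f <- f[f > 0]
  m <- m[m > 0]
  out <- tibble::tibble(
    sex = c(rep("female", length(f)), rep("male", length(m))),
    genotype = c(names(f), names(m)),
    frequency = c(unname(f), unname(m))
  )
  attr(out, "sex_ratio") <- sex_ratio
  attr(out, "generation") <- generation
  class(out) <- c("xelim_population", class(out))
  out
}

pop_vectors <- function(pop) {
  f <- pop$frequency[pop$sex == "female"]
  names(f) <- pop$genotype[pop$sex == "female"]
  m <- pop$frequency[pop$sex == "male"]
  names(m) <- pop$genotype[pop$sex == "male"]
  list(f = f, m = m)
}

#' Build a population state from a frequency table
#'
#' @param data A data frame with columns `sex` (`"female"`/`"male"`),
#'   `genotype` (canonical labels) and `frequency`.  Frequencies are
#'   normalised within each sex.
#' @param config Model configuration; labels are validated by parsing.
#' @return An `xelim_population` tibble.
#' @export
population <- function(data, config) {
  stopifnot(all(c("sex", "genotype", "frequency") %in% names(data)))
  for (i in seq_len(nrow(data))) {
    ind <- parse_genotype(data$genotype[i], config)
    if (ind$sex != data$sex[i]) {
      stop("genotype '", data$genotype[i], "' is not a ", data$sex[i],
           call. = FALSE)
    }
  }
  v <- list(
    f = stats::setNames(data$frequency[data$sex == "female"],
                        data$genotype[data$sex == "female"]),
    m = stats::setNames(data$frequency[data$sex == "male"],
                        data$genotype[data$sex == "male"])
  )
  v$f <- v$f / sum(v$f)
  v$m <- v$m / sum(v$m)
  new_population(v$f, v$m, sex_ratio = 1, generation = 0L)
}

#' Ancestral digenic XX/X0 population
#'
#' The monomorphic starting state: every locus fixed for its ancestral
#' allele, except that with `imprinting_fixed = TRUE` the imprinting locus
#' is fixed for the derived allele (homozygous `gg`) and every male is
#' imprinted, which is the canonical backdrop for the emergence analyses.
#'
#' @param config Model configuration.
#' @param imprinting_fixed Logical; requires locus `g` in the configuration.
#' @return An `xelim_population` with one female and one male class.
#' @examples
#' ancestral_population(model_config())
#' @export
ancestral_population <- function(config, imprinting_fixed = "g" %in% config$loci) {
  alleles <- lapply(config$alleles, function(a) rep(a[1], 2))
  if (imprinting_fixed) {
    if (!"g" %in% config$loci) {
      stop("imprinting_fixed requires locus g", call. = FALSE)
    }
    alleles[["g"]] <- c("g", "g")
  }
  fem <- new_genotype("female", canonical_female(alleles, config))
  mal_alleles <- alleles
  if (config$e_linkage == "X") {
    mal_alleles[["e"]] <- c(alleles[["e"]][1], NA)
  }
  mal <- new_genotype("male", mal_alleles, imprinted = imprinting_fixed)
  new_population(
    stats::setNames(1, format_genotype(fem, config)),
    stats::setNames(1, format_genotype(mal, config)),
    sex_ratio = 1, generation = 0L
  )
}

#' @export
print.xelim_population <- function(x, ...) {
  cat("<xelim_population> generation ", attr(x, "generation"),
      ", SR = ", format(attr(x, "sex_ratio"), digits = 4), "\n", sep = "")
  NextMethod()
}

#' Sex ratio of a population state
#'
#' Male mass divided by female mass of the adult cohort, recorded after
#' viability selection and before per-sex renormalisation.
#' @param pop An `xelim_population`.
#' @return A number.
#' @export
sex_ratio <- function(pop) attr(pop, "sex_ratio")

#' Derived-allele frequency at a locus
#'
#' @param pop An `xelim_population`.
#' @param config Model configuration.
#' @param locus Locus name.
#' @param allele Allele whose frequency is sought (default the derived
#'   allele).
#' @return A tibble with the per-sex allele frequency (copies of `allele`
#'   over allele copies present, hemizygous males counting one X-linked
#'   copy).
#' @export
allele_frequency <- function(pop, config, locus, allele = locus) {
  v <- pop_vectors(pop)
  one_sex <- function(vec) {
    if (length(vec) == 0L) return(NA_real_)
    num <- 0; den <- 0
    for (lab in names(vec)) {
      pr <- parsed(lab, config)$alleles[[locus]]
      pr <- pr[!is.na(pr)]
      num <- num + vec[[lab]] * sum(base_allele(pr) == allele)
      den <- den + vec[[lab]] * length(pr)
    }
    num / den
  }
  tibble::tibble(sex = c("female", "male"),
                 locus = locus, allele = allele,
                 frequency = c(one_sex(v$f), one_sex(v$m)))
}

#' Drop vanished genotype classes
#'
#' Removes classes whose within-sex frequency is below `threshold` and
#' renormalises each sex.
#' @param pop An `xelim_population`.
#' @param threshold Frequency cutoff.
#' @return The pruned `xelim_population`.
#' @export
prune_population <- function(pop, threshold = 1e-6) {
  v <- pop_vectors(pop)
  f <- v$f[v$f >= threshold]
  m <- v$m[v$m >= threshold]
  new_population(f / sum(f), m / sum(m),
                 sex_ratio = attr(pop, "sex_ratio"),
                 generation = attr(pop, "generation"))
}

#' Introduce a new allele by deterministic mass substitution
#'
#' Every copy of the resident allele at the locus, in both sexes and both
#' parental slots, is independently replaced by the new allele with
#' probability `freq`.  This is the deterministic analogue of mutation at
#' population scale: the locus ends in Hardy-Weinberg proportions at
#' `freq`, in linkage equilibrium with every other locus.
#'
#' @param pop An `xelim_population`.
#' @param config Model configuration.
#' @param locus Target locus.
#' @param allele New allele (default the lowercase derived allele).
#' @param freq Per-copy replacement probability in `[0, 1]`.
#' @param replace Resident allele being replaced (default the ancestral
#'   allele; the enhanced inhibitor `e*` instead replaces `e`, from which it
#'   arises).
#' @return The reshaped `xelim_population`.
#' @examples
#' cfg <- model_config()
#' pop <- ancestral_population(cfg)
#' introduce_allele(pop, cfg, "e", freq = 0.05)
#' @export
introduce_allele <- function(pop, config, locus, allele = locus, freq,
                             replace = NULL) {
  if (!locus %in% config$loci) stop("no locus ", locus, call. = FALSE)
  stopifnot(freq >= 0, freq <= 1)
  if (is.null(replace)) {
    replace <- if (allele == "e*") "e" else config$alleles[[locus]][1]
  }
  v <- pop_vectors(pop)
  sub_one <- function(vec) {
    out <- new.env(parent = emptyenv())
    add <- function(lab, p) {
      out[[lab]] <- (if (is.null(out[[lab]])) 0 else out[[lab]]) + p
    }
    for (lab in names(vec)) {
      ind <- parsed(lab, config)
      pr <- ind$alleles[[locus]]
      slots <- which(!is.na(pr) & pr == replace)
      if (length(slots) == 0L) { add(lab, vec[[lab]]); next }
      # independent replacement in each carrying slot
      opts <- expand.grid(rep(list(c(FALSE, TRUE)), length(slots)))
      for (i in seq_len(nrow(opts))) {
        swap <- as.logical(opts[i, ])
        p <- prod(ifelse(swap, freq, 1 - freq))
        if (p == 0) next
        pr2 <- pr
        pr2[slots[swap]] <- allele
        alleles <- ind$alleles
        alleles[[locus]] <- pr2
        if (ind$sex == "female") {
          alleles <- canonical_female(alleles, config)
        }
        ind2 <- new_genotype(ind$sex, alleles, ind$imprinted, ind$x_origin)
        add(format_genotype(ind2, config), vec[[lab]] * p)
      }
    }
    labs <- ls(out)
    stats::setNames(vapply(labs, function(l) out[[l]], 0), labs)
  }
  new_population(sub_one(v$f), sub_one(v$m),
                 sex_ratio = attr(pop, "sex_ratio"),
                 generation = attr(pop, "generation"))
}
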