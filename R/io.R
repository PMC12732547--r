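# Tabular export and the command-line entry point.

#' Write a trajectory, grid or cross table to a delimited file
#'
#' @param x An `xelim_trajectory`, `xelim_grid`, `xelim_scenario_result`,
#'   `xelim_cross` or plain data frame.
#' @param path Output file.
#' @param sep Field separator (default tab).
#' @param digits Printed precision for frequencies (default 4 decimals;
#'   internal state keeps full double precision).
#' @return Invisibly, the data frame written.
#' @export
write_xelim <- function(x, path, sep = "\t", digits = 4) {
  df <- if (is.data.frame(x)) x else tidy(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(col) round(col, digits))
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

cli_usage <- function() {
  paste(
    "usage: xelim <command> [options]",
    "",
    "commands:",
    "  run      --scenario NAME [--catalogue FILE] [--out FILE]",
    "           run one catalogue scenario; writes the stage trajectory",
    "           table (generation, sex, genotype, frequency, sex_ratio)",
    "  grid     [--catalogue FILE] [--out FILE]",
    "           run every catalogue scenario; writes the outcome matrix",
    "  cross    --mother LABEL --father LABEL [--variant V] [--loci L]",
    "           [--dominance s=recessive,r=recessive] [--out FILE]",
    "           print a single-pair brood table",
    "  classify --state FILE [--variant V] [--loci L] [--dominance ...]",
    "           classify a population state table (sex, genotype,",
    "           frequency)",
    sep = "\n")
}

cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      opts[[substring(a, 3)]] <- args[[i + 1L]]
      i <- i + 2L
    } else i <- i + 1L
  }
  opts
}

cli_config <- function(opts) {
  dom <- c(s = "recessive", r = "recessive", g = "recessive",
           c = "recessive")
  if (!is.null(opts$dominance)) {
    for (kv in strsplit(opts$dominance, ",")[[1]]) {
      p <- strsplit(kv, "=")[[1]]
      dom[[p[1]]] <- p[2]
    }
  }
  loci <- if (!is.null(opts$loci)) strsplit(opts$loci, ",")[[1]]
          else c("e", "s", "r", "g")
  model_config(variant = opts$variant %||% "two_factor", loci = loci,
               dominance = dom)
}

#' Command-line driver
#'
#' Thin dispatcher behind the `inst/cli/xelim.R` script: `run` executes one
#' catalogue scenario and writes its trajectory table, `grid` writes the
#' qualitative outcome matrix of the whole catalogue, `cross` prints a
#' single-pair brood table, `classify` classifies a population state read
#' from a delimited file.  Stage events (introductions, convergence,
#' extinction) are logged to standard error.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) { message(cli_usage()); return(1L) }
  cmd <- args[[1]]
  opts <- cli_opts(args[-1])
  out <- opts$out
  status <- tryCatch({
    switch(cmd,
      run = {
        cat_path <- opts$catalogue %||% catalogue_path()
        scns <- scenario_catalogue(cat_path)
        if (is.null(opts$scenario) || !opts$scenario %in% names(scns)) {
          stop("unknown scenario; available: ",
               paste(names(scns), collapse = ", "), call. = FALSE)
        }
        res <- run_scenario(scns[[opts$scenario]])
        for (k in seq_along(res$stages)) {
          s <- res$stages[[k]]
          message("stage ", k, " (", s$locus, "): ", s$fate, ", ",
                  s$generations, " generations, ",
                  if (s$converged) "converged" else "not converged",
                  if (!is.null(s$extinct)) paste0(", EXTINCT (no ",
                                                  s$extinct, "s)"))
        }
        message("outcome: ", res$final_class)
        tab <- purrr::map_dfr(seq_along(res$stages), function(k) {
          dplyr::mutate(tidy(res$stages[[k]]$trajectory), stage = k,
                        .before = 1)
        })
        if (!is.null(out)) write_xelim(tab, out) else print(tab)
        0L
      },
      grid = {
        cat_path <- opts$catalogue %||% catalogue_path()
        g <- run_grid(scenario_catalogue(cat_path))
        tab <- tidy(g)
        if (!is.null(out)) write_xelim(tab, out) else print(tab, n = Inf)
        0L
      },
      cross = {
        config <- cli_config(opts)
        tab <- cross(opts$mother, opts$father, config)
        message("daughters: ", format(attr(tab, "daughters"), digits = 4),
                "  sons: ", format(attr(tab, "sons"), digits = 4))
        if (!is.null(out)) write_xelim(tab, out) else print(tab, n = Inf)
        0L
      },
      classify = {
        config <- cli_config(opts)
        df <- utils::read.delim(opts$state, sep = "\t",
                                stringsAsFactors = FALSE)
        pop <- population(df, config)
        cl <- classify_population(pop, config)
        cat(cl$class, "\n")
        0L
      },
      { message(cli_usage()); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  status
}
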