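#' Crossing-scheme configurations
#'
#' A scheme configuration describes one marker-assisted backcross program:
#' an ordered plan of backcross generations (population size, whether the
#' generation is genotyped, and the selection-region kind applied in it),
#' the line-development method (doubled haploids or two generations of
#' selfing to F3), and the size of the line generation. The final 100-IL
#' selection on target segments is common to all schemes.
#'
#' `scheme_config()` builds a configuration from scratch; most users will
#' take entries from the built-in catalogue via [builtin_scheme()].
#'
#' @param name Scheme name.
#' @param series One of `"basic"`, `"high_intensity"`, `"final_selection"`,
#'   `"increasing"`.
#' @param line_method `"DH"` or `"F3"`.
#' @param strategy Strategy code: one letter per selected backcross
#'   generation, over C (complete chromosomes), H (chromosome halves),
#'   S (target segments), e.g. `"CH"` selects chromosomes in BC1 and halves
#'   in BC2.
#' @param bc_sizes Integer vector of total population sizes per backcross
#'   generation (length 2 or 3).
#' @param select_in Logical vector, same length: is selection (and hence
#'   genotyping) carried out in that backcross generation?
#' @param lines_n Size of the line generation (always genotyped).
#' @param m_final For DH schemes with selection in the final backcross
#'   generation: total number selected there (defaults to `lines_n`).
#' @return A `scheme_config` object.
#' @export
scheme_config <- function(name, series, line_method, strategy, bc_sizes,
                          select_in, lines_n, m_final = lines_n) {
  line_method <- match.arg(line_method, c("DH", "F3"))
  series <- match.arg(series, c("basic", "high_intensity",
                                "final_selection", "increasing"))
  strategy <- toupper(strategy)
  letters_ <- strsplit(strategy, "")[[1]]
  if (!all(letters_ %in% c("C", "H", "S")))
    stop("strategy must use letters C, H, S only: ", strategy)
  if (length(letters_) != sum(select_in))
    stop("strategy ", strategy, " has ", length(letters_),
         " letters but ", sum(select_in),
         " backcross generations with selection")
  stopifnot(length(bc_sizes) == length(select_in),
            all(bc_sizes >= 1), lines_n >= 1)
  kinds <- character(length(bc_sizes))
  kinds[!select_in] <- "none"
  kinds[select_in] <- c(chromosome = "chromosome", half = "half",
                        segment = "segment")[
    c(C = "chromosome", H = "half", S = "segment")[letters_]]
  plans <- tibble::tibble(
    generation = paste0("BC", seq_along(bc_sizes)),
    size = as.integer(bc_sizes),
    genotyped = select_in,
    selection = kinds,
    final = seq_along(bc_sizes) == length(bc_sizes)
  )
  structure(list(name = name, series = series, line_method = line_method,
                 strategy = strategy, plans = plans,
                 lines_n = as.integer(lines_n),
                 m_final = as.integer(m_final)),
            class = "scheme_config")
}

#' @export
print.scheme_config <- function(x, ...) {
  cat("<scheme_config> ", x$name, ": ", x$series, " series, ",
      nrow(x$plans), " backcross generations (N = ",
      paste(x$plans$size, collapse = "/"), "), strategy ", x$strategy,
      ", ", x$lines_n, " ", x$line_method, " lines, HT = ",
      ht_count(x), "\n", sep = "")
  invisible(x)
}

region_count <- function(kind, map = il_map()) {
  switch(kind, chromosome = map$n_chromosomes,
         half = 2L * map$n_chromosomes, segment = map$n_segments,
         stop("unknown region kind: ", kind))
}

#' Built-in crossing-scheme catalogue
#'
#' The catalogue holds 32 schemes: four simulation series (basic, high
#' selection intensity, selection in the final backcross generation,
#' increasing population sizes) for both DH and F3 line development.
#' Population-size profiles: basic schemes keep N = 360 per backcross
#' generation (selection in all but the final backcross generation);
#' high-intensity schemes double every generation to N = 720 with unchanged
#' numbers selected; final-selection schemes also select in the final
#' backcross generation, which for DH schemes is doubled to 720 so that 360
#' DH lines remain, while F3 schemes keep 360 throughout; increasing-size
#' schemes grow 120/240/720 over three backcross generations with selection
#' in every one. The line generation (360 lines; 720 for high intensity) is
#' always genotyped.
#'
#' Scheme names encode series, backcross depth, line method and strategy,
#' e.g. `"basic-bc3-dh-hh"` or `"incr-bc3-f3-hhs"`.
#'
#' @param name Catalogue key.
#' @return `builtin_scheme()`: a [scheme_config()]. `scheme_catalogue()`: a
#'   tibble listing all schemes with their HT-assay totals.
#' @examples
#' builtin_scheme("basic-bc2-dh-c")
#' scheme_catalogue()
#' @export
builtin_scheme <- function(name) {
  cat_ <- scheme_definitions()
  if (!name %in% names(cat_))
    stop("unknown scheme '", name, "'; see scheme_catalogue()")
  do.call(scheme_config, c(list(name = name), cat_[[name]]))
}

#' @rdname builtin_scheme
#' @export
scheme_catalogue <- function() {
  defs <- scheme_definitions()
  purrr::map_dfr(names(defs), function(nm) {
    cfg <- builtin_scheme(nm)
    tibble::tibble(name = nm, series = cfg$series,
                   line_method = cfg$line_method,
                   n_backcross = nrow(cfg$plans),
                   strategy = cfg$strategy,
                   bc_sizes = paste(cfg$plans$size, collapse = "/"),
                   lines_n = cfg$lines_n,
                   ht = ht_count(cfg))
  })
}

scheme_definitions <- function() {
  defs <- list()
  add <- function(nm, ...) defs[[nm]] <<- list(...)
  for (lm in c("dh", "f3")) {
    LM <- toupper(lm)
    # basic: constant N = 360, no selection in the final backcross generation
    for (st in c("C", "H"))
      add(paste0("basic-bc2-", lm, "-", tolower(st)),
          series = "basic", line_method = LM, strategy = st,
          bc_sizes = c(360, 360), select_in = c(TRUE, FALSE), lines_n = 360)
    for (st in c("CC", "HH", "CH"))
      add(paste0("basic-bc3-", lm, "-", tolower(st)),
          series = "basic", line_method = LM, strategy = st,
          bc_sizes = c(360, 360, 360), select_in = c(TRUE, TRUE, FALSE),
          lines_n = 360)
    # high selection intensity: N doubled to 720 everywhere, same numbers kept
    for (st in c("CC", "HH", "CH"))
      add(paste0("high-bc3-", lm, "-", tolower(st)),
          series = "high_intensity", line_method = LM, strategy = st,
          bc_sizes = c(720, 720, 720), select_in = c(TRUE, TRUE, FALSE),
          lines_n = 720)
    # selection in the final backcross generation; DH doubles the final BC
    fin_last <- if (LM == "DH") 720 else 360
    for (st in c("CC", "HH", "CH"))
      add(paste0("final-bc2-", lm, "-", tolower(st)),
          series = "final_selection", line_method = LM, strategy = st,
          bc_sizes = c(360, fin_last), select_in = c(TRUE, TRUE),
          lines_n = 360)
    for (st in c("CCC", "HHH", "CHH"))
      add(paste0("final-bc3-", lm, "-", tolower(st)),
          series = "final_selection", line_method = LM, strategy = st,
          bc_sizes = c(360, 360, fin_last), select_in = c(TRUE, TRUE, TRUE),
          lines_n = 360)
    # increasing population sizes with selection in the final BC generation
    for (st in c("HHH", "HHS"))
      add(paste0("incr-bc3-", lm, "-", tolower(st)),
          series = "increasing", line_method = LM, strategy = st,
          bc_sizes = c(120, 240, 720), select_in = c(TRUE, TRUE, TRUE),
          lines_n = 360)
  }
  defs
}

#' High-throughput assay accounting
#'
#' One HT assay genotypes one individual at all markers of the map. The
#' total for a scheme is the closed-form sum of the sizes of all genotyped
#' generations: every backcross generation in which selection is carried
#' out, plus the line generation (always genotyped for the final 100-IL
#' selection). No simulation is involved.
#'
#' @param cfg A [scheme_config()].
#' @return Integer assay count.
#' @examples
#' ht_count(builtin_scheme("basic-bc3-dh-cc"))   # 1080
#' @export
ht_count <- function(cfg) {
  stopifnot(inherits(cfg, "scheme_config"))
  sum(cfg$plans$size[cfg$plans$genotyped]) + cfg$lines_n
}
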