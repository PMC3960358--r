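#' Read a crossing-scheme configuration file
#'
#' Loads a scheme description from YAML or JSON. Two layouts are accepted:
#' the compact form with the [scheme_config()] arguments
#' (`name`, `series`, `line_method`, `strategy`, `bc_sizes`, `select_in`,
#' `lines_n`, optional `m_final`), or an explicit `generations` list with
#' one entry per backcross generation (`label`, `size`, `genotyped`,
#' `selection` — `none`/`chromosome`/`half`/`segment`). An optional `map`
#' block (`chromosomes`, `length_cM`, `marker_spacing_cM`, `segment_cM`)
#' overrides the default genetic map and is returned as the `"map"`
#' attribute.
#'
#' @param path File path; format chosen by extension (`.json` vs
#'   `.yml`/`.yaml`).
#' @return A [scheme_config()]; if the file has a `map` block, the
#'   corresponding [il_map()] is attached as attribute `"map"`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("name: demo", "series: basic", "line_method: DH",
#'              "strategy: C", "bc_sizes: [60, 60]",
#'              "select_in: [yes, no]", "lines_n: 60"), f)
#' read_scheme_config(f)
#' @export
read_scheme_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(x$generations)) {
    gens <- x$generations
    if (is.data.frame(gens)) gens <- split(gens, seq_len(nrow(gens)))
    sizes <- vapply(gens, function(g) as.integer(g$size), 1L)
    kinds <- vapply(gens, function(g) as.character(g$selection %||% "none"),
                    "")
    x$bc_sizes <- sizes
    x$select_in <- kinds != "none"
    x$strategy <- paste(c(chromosome = "C", half = "H", segment = "S")[
      kinds[kinds != "none"]], collapse = "")
  }
  cfg <- scheme_config(
    name = x$name %||% basename(path),
    series = x$series %||% "basic",
    line_method = x$line_method,
    strategy = x$strategy,
    bc_sizes = as.integer(unlist(x$bc_sizes)),
    select_in = as.logical(unlist(x$select_in)),
    lines_n = as.integer(x$lines_n),
    m_final = as.integer(x$m_final %||% x$lines_n)
  )
  if (!is.null(x$map)) {
    attr(cfg, "map") <- il_map(
      n_chromosomes = x$map$chromosomes %||% 10,
      chrom_length = x$map$length_cM %||% 200,
      marker_spacing = x$map$marker_spacing_cM %||% 1,
      segment_length = x$map$segment_cM %||% 20)
  }
  cfg
}
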