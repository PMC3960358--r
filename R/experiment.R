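#' Replicated simulation of crossing schemes
#'
#' Runs each scheme for `n_replicates` independent replicates and aggregates
#' the nine population measures into per-scheme means with Monte-Carlo
#' standard errors. Replicates run on deterministic per-replicate seed
#' substreams derived from the master seed, so any single replicate can be
#' re-run in isolation (`replicate_seed()`), and the whole experiment is
#' bit-reproducible given `seed`.
#'
#' @param schemes Character vector of catalogue names, a single
#'   [scheme_config()], or a list of them.
#' @param n_replicates Replicates per scheme (1000 reproduces full-scale
#'   reports; 200 keeps Monte-Carlo SEs of the reported means well below
#'   their printed precision at desk scale).
#' @param seed Master seed (integer).
#' @param map The [il_map()].
#' @param weights Selection-index weights, see [selection_index()].
#' @param verbose Print one line per scheme as it completes?
#' @return An object of class `il_experiment` with `replicates` (tibble:
#'   one row per scheme x replicate with all measures) and `summary`
#'   (tibble: per-scheme means and `se_*` columns).
#' @examples
#' \donttest{
#' ex <- run_replications("basic-bc2-dh-c", n_replicates = 3, seed = 7)
#' tidy(ex)
#' }
#' @export
run_replications <- function(schemes, n_replicates = 1000, seed = 1,
                             map = il_map(), weights = c(1, 1),
                             verbose = FALSE) {
  cfgs <- normalize_schemes(schemes)
  stopifnot(n_replicates >= 1)
  reps <- vector("list", length(cfgs))
  for (k in seq_along(cfgs)) {
    cfg <- cfgs[[k]]
    rows <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      run <- run_scheme(cfg, map = map,
                        seed = replicate_seed(seed, cfg$name, r),
                        weights = weights)
      rows[[r]] <- measure_row(run$ils, ht = run$ht_total, map = map)
    }
    reps[[k]] <- dplyr::bind_cols(
      tibble::tibble(scheme = cfg$name, replicate = seq_len(n_replicates)),
      dplyr::bind_rows(lapply(rows, tibble::as_tibble)))
    if (verbose)
      message("scheme ", cfg$name, ": ", n_replicates, " replicates done")
  }
  replicates <- dplyr::bind_rows(reps)
  structure(list(replicates = replicates,
                 summary = summarize_replicates(replicates),
                 n_replicates = n_replicates, seed = seed),
            class = "il_experiment")
}

normalize_schemes <- function(schemes) {
  if (inherits(schemes, "scheme_config")) return(list(schemes))
  if (is.character(schemes)) return(lapply(schemes, builtin_scheme))
  stopifnot(is.list(schemes),
            all(vapply(schemes, inherits, TRUE, "scheme_config")))
  schemes
}

#' @rdname run_replications
#' @param scheme Scheme name.
#' @param replicate Replicate number.
#' @export
replicate_seed <- function(seed, scheme, replicate) {
  # deterministic substream: scheme name hashed onto a 31-bit lattice
  h <- sum(utf8ToInt(scheme) * seq_along(utf8ToInt(scheme)))
  as.integer((as.double(seed) * 48271 + h * 8191 + replicate * 7919) %%
               2147483647) + 1L
}

summarize_replicates <- function(replicates) {
  cols <- c("C_D", "depth", "N_D", "R", "S_D", "L_D",
            "lambda_D", "Z_C", "Z_S", "HT")
  out <- replicates |>
    dplyr::group_by(.data$scheme) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(
        dplyr::all_of(cols),
        list(mean = ~ mean(.x, na.rm = TRUE),
             se = ~ stats::sd(.x, na.rm = TRUE) / sqrt(dplyr::n())),
        .names = "{.col}__{.fn}"),
      .groups = "drop")
  names(out) <- sub("^(.*)__mean$", "\\1", names(out))
  names(out) <- sub("^(.*)__se$", "se_\\1", names(out))
  out
}

#' @export
print.il_experiment <- function(x, ...) {
  cat("<il_experiment> ", dplyr::n_distinct(x$replicates$scheme),
      " scheme(s) x ", x$n_replicates, " replicates (seed ", x$seed, ")\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidiers for replicated experiments
#'
#' `tidy()` returns the per-scheme summary (means and Monte-Carlo standard
#' errors of all measures); `glance()` returns one row describing the
#' experiment.
#'
#' @param x An `il_experiment`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.il_experiment <- function(x, ...) x$summary

#' @rdname tidy.il_experiment
#' @export
glance.il_experiment <- function(x, ...) {
  tibble::tibble(n_schemes = dplyr::n_distinct(x$replicates$scheme),
                 n_replicates = x$n_replicates,
                 seed = x$seed,
                 min_C_D = min(x$summary$C_D),
                 max_lambda_D = max(x$summary$lambda_D))
}

#' Formatted measure table over schemes
#'
#' One row per scheme with the measure columns in conventional order,
#' rounded for reporting (one decimal; N_D and HT as integers). Schemes are
#' grouped by line method and series, in catalogue order.
#'
#' @param x An `il_experiment` (or its summary tibble).
#' @param digits Decimal places for the rounded measures.
#' @return A tibble with columns `scheme`, `series`, `line_method`, the ten
#'   measure columns.
#' @export
measure_table <- function(x, digits = 1) {
  s <- if (inherits(x, "il_experiment")) x$summary else x
  cat_ <- scheme_catalogue()
  out <- s |>
    dplyr::left_join(cat_[, c("name", "series", "line_method")],
                     by = c(scheme = "name")) |>
    dplyr::mutate(
      dplyr::across(c("C_D", "R", "S_D", "L_D", "depth",
                      "lambda_D", "Z_C", "Z_S"), ~ round(.x, digits)),
      N_D = round(.data$N_D), HT = as.integer(round(.data$HT))) |>
    dplyr::select("scheme", "series", "line_method", "C_D", "depth",
                  "N_D", "R", "S_D", "L_D", "lambda_D", "Z_C", "Z_S", "HT")
  ord <- match(out$scheme, cat_$name)
  out[order(is.na(ord), ord), ]
}

#' Quantiles of the per-replicate Z_S distribution
#'
#' Underlying numbers of the Z_S boxplot: per scheme, the quartiles and
#' whisker range of the donor genome proportion of the target segments over
#' replicates.
#'
#' @param x An `il_experiment`.
#' @param probs Quantile probabilities.
#' @return A tibble `scheme`, `prob`, `Z_S`.
#' @export
zs_quantiles <- function(x, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  stopifnot(inherits(x, "il_experiment"))
  x$replicates |>
    dplyr::group_by(.data$scheme) |>
    dplyr::reframe(prob = probs,
                   Z_S = stats::quantile(.data$Z_S, probs, names = FALSE))
}
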