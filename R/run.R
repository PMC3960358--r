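#' Run a crossing scheme from F1 to a 100-IL population
#'
#' Executes one replicate of a marker-assisted backcross program: the F1 of
#' a homozygous donor and recipient is backcrossed to the recipient; in each
#' backcross generation the configured total population size is split
#' equally over the active lineage branches (remainders to the
#' lowest-indexed branches); where the plan calls for selection, the best
#' individuals per selection region (by [selection_index()]) are kept and
#' each becomes the parent of one branch of the next generation. After the
#' final backcross generation, lines are developed either as doubled
#' haploids (one DH per backcross individual) or by two generations of
#' selfing (one F2 and one F3 per family slot), and [select_final_ils()]
#' assigns the best line to each of the 100 target segments.
#'
#' Genotyping is accounted per generation: every backcross generation in
#' which selection occurs, and the line generation, consume one HT assay per
#' individual.
#'
#' @param cfg A [scheme_config()], e.g. from [builtin_scheme()].
#' @param map The [il_map()] (default maize-style map).
#' @param seed Optional integer seed set before the run.
#' @param weights Selection-index weights, see [selection_index()].
#' @param keep_lineage Record per-individual pedigree and selection events?
#' @param split_finer If `TRUE`, a generation whose selection uses a finer
#'   region system than the current branches first splits every branch's
#'   offspring evenly into per-region sub-populations and each region
#'   selects only within its own; with `FALSE` (default) every region
#'   selects from its branch's full sub-population. Exposed for sensitivity
#'   analysis of the branching design.
#' @param distinct Passed to [select_per_region()]: an individual is
#'   selected for at most one region (default `TRUE`; a backcross individual
#'   founds exactly one sub-program or line).
#' @return An object of class `il_run`: list with `ils` (an
#'   `il_population`), `ledger` (tibble of per-generation genotyping counts),
#'   `ht_total`, `cfg`, and optionally `lineage`.
#' @examples
#' \donttest{
#' run <- run_scheme(builtin_scheme("basic-bc2-dh-c"), seed = 1)
#' run$ht_total   # 720
#' }
#' @export
run_scheme <- function(cfg, map = il_map(), seed = NULL, weights = c(1, 1),
                       keep_lineage = FALSE, split_finer = FALSE,
                       distinct = TRUE) {
  stopifnot(inherits(cfg, "scheme_config"), inherits(map, "il_map"))
  if (!is.null(seed)) set.seed(seed)
  if (map$n_segments < 1) stop("map has no target segments")

  parents <- make_f1(map)               # BC1 starts from exactly one F1
  ledger <- list()
  lineage <- if (keep_lineage) list() else NULL
  offspring <- NULL

  for (t in seq_len(nrow(cfg$plans))) {
    plan <- cfg$plans[t, ]
    sizes <- split_evenly(plan$size, parents$n)
    pidx <- rep(seq_len(parents$n), times = sizes)
    offspring <- backcross(parents, map, parents = pidx,
                           generation = plan$generation)
    ledger[[plan$generation]] <- list(
      generation = plan$generation, n = plan$size,
      genotyped = plan$genotyped)
    if (keep_lineage)
      lineage[[plan$generation]] <- tibble::tibble(
        generation = plan$generation,
        individual = seq_len(offspring$n),
        parent = pidx, branch = offspring$branch)

    if (plan$selection != "none") {
      regions <- region_partition(map, plan$selection)
      pool <- selection_pools(offspring, regions, map,
                              split_finer = split_finer)
      m_per_region <-
        if (plan$final && cfg$line_method == "DH")
          split_evenly(cfg$m_final, nrow(regions))
        else 1L
      sel <- select_per_region(offspring, regions, m_per_region,
                               pool = pool, weights = weights,
                               distinct = distinct)
      parents <- subset_population(offspring, sel$individual, map)
      parents$branch_kind <- plan$selection
      parents$branch <- as.integer(sel$region)
      if (plan$selection != "segment") {
        # lineage branch for the final IL assembly: the finest chromosome- or
        # half-level region system selected for; segment-level selection only
        # structures parents within a sub-program and does not narrow the
        # candidate pool of the library assembly
        parents$origin_kind <- plan$selection
        parents$origin <- as.integer(sel$region)
      }
      if (keep_lineage)
        lineage[[paste0(plan$generation, "-selected")]] <- tibble::tibble(
          generation = paste0(plan$generation, "-selected"),
          individual = sel$individual, parent = sel$individual,
          branch = sel$region, index = sel$index)
    } else {
      parents <- offspring
    }
  }

  # line development from the final backcross parents
  if (cfg$line_method == "DH") {
    lines <- make_dh(parents, map, generation = "DH")
  } else {
    final_selected <- cfg$plans$selection[nrow(cfg$plans)] != "none"
    slots <- if (!final_selected) rep(1L, parents$n)
             else split_evenly(cfg$lines_n, parents$n)
    fam <- rep(seq_len(parents$n), times = slots)
    f2 <- self_population(parents, map, parents = fam, generation = "F2")
    lines <- self_population(f2, map, generation = "F3")
  }
  if (lines$n != cfg$lines_n)
    stop("scheme ", cfg$name, " produced ", lines$n, " lines; expected ",
         cfg$lines_n)
  ledger[[lines$generation]] <- list(
    generation = lines$generation, n = lines$n, genotyped = TRUE)
  if (keep_lineage)
    lineage[[lines$generation]] <- tibble::tibble(
      generation = lines$generation, individual = seq_len(lines$n),
      parent = NA_integer_, branch = lines$branch)

  ils <- select_final_ils(lines, map, weights = weights)
  ledger <- dplyr::bind_rows(lapply(ledger, tibble::as_tibble))
  structure(list(ils = ils, ledger = ledger,
                 ht_total = sum(ledger$n[ledger$genotyped]),
                 cfg = cfg,
                 lineage = if (keep_lineage) dplyr::bind_rows(lineage)),
            class = "il_run")
}

#' @export
print.il_run <- function(x, ...) {
  cat("<il_run> scheme ", x$cfg$name, ": ", x$ils$n,
      " ILs, HT assays = ", x$ht_total, "\n", sep = "")
  invisible(x)
}

# split `total` into `k` integer parts, as equal as possible, remainders
# to the lowest-indexed parts (deterministic)
split_evenly <- function(total, k) {
  base <- total %/% k
  rem <- total %% k
  as.integer(base + (seq_len(k) <= rem))
}

# candidate pool per selection region. The first selected generation is one
# undivided population (every region selects from all individuals). Once
# branches exist, selection for the same region system stays within the
# branch; selection for a finer system first splits each branch's
# sub-population evenly over its child regions (remainders to the
# lowest-indexed), mirroring the per-region sub-programs of a branched
# crossing scheme, and each region then selects from its own sub-population.
selection_pools <- function(pop, regions, map, split_finer = TRUE) {
  if (pop$branch_kind == "none") return(NULL)
  rank <- c(chromosome = 1, half = 2, segment = 3)
  if (rank[[pop$branch_kind]] > rank[[regions$kind[1]]]) return(NULL)
  anc <- ancestor_region(regions, pop$branch_kind, map)
  if (!split_finer || rank[[pop$branch_kind]] == rank[[regions$kind[1]]])
    return(lapply(seq_len(nrow(regions)),
                  function(r) which(pop$branch == anc[r])))
  assigned <- rep(NA_integer_, pop$n)
  for (b in unique(anc)) {
    children <- regions$region[anc == b]
    rows <- which(pop$branch == b)
    if (length(rows) == 0) next
    counts <- split_evenly(length(rows), length(children))
    assigned[rows] <- rep(children, counts)
  }
  lapply(regions$region, function(r) which(assigned == r))
}

# id of the region of kind `kind` containing each region in `regions`
# (midpoint-based; region systems nest for the supported kinds)
ancestor_region <- function(regions, kind, map) {
  if (kind == regions$kind[1]) return(regions$region)
  mid <- (regions$start + regions$end) / 2   # within-chromosome cM
  switch(kind,
    chromosome = regions$chrom,
    half = (regions$chrom - 1L) * 2L +
      ifelse(mid < map$chrom_length / 2, 1L, 2L),
    segment = (regions$chrom - 1L) * map$segments_per_chrom +
      findInterval(mid, seq(0, map$chrom_length, by = map$segment_length)))
}
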