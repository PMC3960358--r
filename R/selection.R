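#' Selection index for a chromosome region
#'
#' The index for individual i and selection region R is
#' \deqn{i_R = d(R) + (1 - d(B))}
#' where d(R) is the donor-allele dosage of the region and d(B) the dosage of
#' the background B (all markers outside the region, genome-wide). Both terms
#' carry unit weight: donor content of the selection region and recovery of
#' the recipient background count equally. The index ranges over `[0, 2]`;
#' the recipient scores 1, and 2 is attained only by genotypes homozygous
#' donor across the region and recipient everywhere else.
#'
#' @param pop An `il_pop`.
#' @param region One row of [region_partition()] (or any list with
#'   `col_start`, `col_end`).
#' @param weights Length-2 numeric, weights of the region-donor and
#'   background-recipient terms (default `c(1, 1)`; exposed for sensitivity
#'   analysis).
#' @return Numeric vector of scores, one per individual.
#' @export
selection_index <- function(pop, region, weights = c(1, 1)) {
  stopifnot(inherits(pop, "il_pop"))
  m <- region$col_end - region$col_start + 1L
  M <- ncol(pop$H1)
  if (m < 1L || m > M) stop("selection region is empty or malformed")
  s <- cpp_block_rowsums(pop$H1, pop$H2, region$col_start, region$col_end)
  tot <- cpp_block_rowsums(pop$H1, pop$H2, 1L, M)
  d_region <- s / (2 * m)
  d_bg <- if (M > m) (tot - s) / (2 * (M - m)) else 0
  weights[1] * d_region + weights[2] * (1 - d_bg)
}

#' Truncation selection per region
#'
#' For each region independently, the `m_per_region` individuals with the
#' highest selection index are selected; exact ties are broken by a seeded
#' uniform draw. The same individual may be selected for several regions.
#' When `pool` is supplied, candidates for each region are restricted to the
#' given row indices (used to keep selection within a lineage branch).
#'
#' @param pop An `il_pop`.
#' @param regions Tibble from [region_partition()].
#' @param m_per_region Number selected per region: scalar or one value per
#'   region.
#' @param pool Optional list (one element per region) of candidate row
#'   indices.
#' @param weights Passed to [selection_index()].
#' @param distinct If `TRUE`, an individual can be selected for at most one
#'   region: (region, individual) pairs are assigned greedily in decreasing
#'   index order, skipping individuals already taken. Required whenever one
#'   selected individual founds exactly one line (DH derivation); with
#'   `FALSE` (default) regions select independently and may share
#'   individuals.
#' @return A tibble with columns `region`, `rank`, `individual` (row index in
#'   `pop`) and `index` (the score).
#' @export
select_per_region <- function(pop, regions, m_per_region = 1, pool = NULL,
                              weights = c(1, 1), distinct = FALSE) {
  stopifnot(inherits(pop, "il_pop"))
  if (pop$n == 0) stop("cannot select from an empty population")
  m_per_region <- rep_len(m_per_region, nrow(regions))
  tot <- cpp_block_rowsums(pop$H1, pop$H2, 1L, ncol(pop$H1))
  M <- ncol(pop$H1)
  n_reg <- nrow(regions)
  cands <- scores <- vector("list", n_reg)
  for (r in seq_len(n_reg)) {
    cand <- if (is.null(pool)) seq_len(pop$n) else pool[[r]]
    if (length(cand) == 0)
      stop("no selection candidates for region ", regions$region[r],
           " (", regions$kind[r], ") in generation ", pop$generation)
    m_r <- regions$col_end[r] - regions$col_start[r] + 1L
    s <- cpp_block_rowsums(pop$H1, pop$H2,
                           regions$col_start[r], regions$col_end[r])[cand]
    cands[[r]] <- cand
    scores[[r]] <- weights[1] * s / (2 * m_r) +
      weights[2] * (1 - (tot[cand] - s) / (2 * (M - m_r)))
  }
  if (!distinct) {
    out_region <- out_rank <- out_ind <- out_index <- vector("list", n_reg)
    for (r in seq_len(n_reg)) {
      k <- min(m_per_region[r], length(cands[[r]]))
      ord <- order(scores[[r]], stats::runif(length(cands[[r]])),
                   decreasing = TRUE)[seq_len(k)]
      out_region[[r]] <- rep(regions$region[r], k)
      out_rank[[r]] <- seq_len(k)
      out_ind[[r]] <- cands[[r]][ord]
      out_index[[r]] <- scores[[r]][ord]
    }
    return(tibble::tibble(
      region = unlist(out_region), rank = unlist(out_rank),
      individual = unlist(out_ind), index = unlist(out_index)))
  }
  pair_region <- rep(regions$region, lengths(cands))
  pair_ind <- unlist(cands)
  pair_score <- unlist(scores)
  ord <- order(-pair_score, stats::runif(length(pair_score)))
  taken <- logical(pop$n)
  n_sel <- integer(n_reg)
  sel_region <- integer(0)
  sel_ind <- integer(0)
  sel_index <- numeric(0)
  for (i in ord) {
    r <- pair_region[i]
    if (n_sel[r] >= m_per_region[r] || taken[pair_ind[i]]) next
    n_sel[r] <- n_sel[r] + 1L
    taken[pair_ind[i]] <- TRUE
    sel_region <- c(sel_region, r)
    sel_ind <- c(sel_ind, pair_ind[i])
    sel_index <- c(sel_index, pair_score[i])
  }
  if (any(n_sel < pmin(m_per_region, lengths(cands))))
    stop("insufficient distinct candidates in generation ", pop$generation)
  o <- order(sel_region, -sel_index)
  tibble::tibble(region = sel_region[o],
                 rank = unlist(lapply(n_sel, seq_len)),
                 individual = sel_ind[o], index = sel_index[o])
}

#' Assemble the final introgression-line population
#'
#' Selects the 100 introgression lines: every target segment is assigned one
#' candidate line by its segment-level selection index i_S, and each
#' physical line can serve only one segment (the library consists of 100
#' distinct ILs). Assignment is greedy on the index: (segment, line) pairs
#' are taken in decreasing score order, a pair being accepted when both the
#' segment and the line are still free. When the lines carry branch labels
#' from earlier region-based selection, candidates for a segment are the
#' lines whose branch region contains that segment; segments whose branch
#' pool is empty or exhausted fall back to the best unused line in the whole
#' line set. Exact score ties are broken by a seeded uniform draw.
#'
#' @param lines An `il_pop` of candidate lines (DH or F3).
#' @param map The [il_map()].
#' @param weights Passed to [selection_index()].
#' @return An object of class `il_population`: the selected ILs (one per
#'   target segment) with their segment assignment, the map, and the
#'   segment-index score of each chosen line.
#' @export
select_final_ils <- function(lines, map, weights = c(1, 1)) {
  stopifnot(inherits(lines, "il_pop"), inherits(map, "il_map"))
  segs <- region_partition(map, "segment")
  n_seg <- nrow(segs)
  if (lines$n < n_seg)
    stop("need at least ", n_seg, " candidate lines, got ", lines$n)
  tot <- cpp_block_rowsums(lines$H1, lines$H2, 1L, ncol(lines$H1))
  M <- ncol(lines$H1)
  seg_score <- function(s, cand) {
    m_r <- segs$col_end[s] - segs$col_start[s] + 1L
    bs <- cpp_block_rowsums(lines$H1, lines$H2,
                            segs$col_start[s], segs$col_end[s])[cand]
    weights[1] * bs / (2 * m_r) +
      weights[2] * (1 - (tot[cand] - bs) / (2 * (M - m_r)))
  }
  # candidate (segment, line) pairs within branch pools
  cands <- lapply(seq_len(n_seg), function(s) branch_pool(lines, map, s))
  pair_seg <- rep(seq_len(n_seg), lengths(cands))
  pair_line <- unlist(cands)
  pair_score <- unlist(lapply(seq_len(n_seg),
                              function(s) seg_score(s, cands[[s]])))
  ord <- order(-pair_score, stats::runif(length(pair_score)))
  pick <- rep(NA_integer_, n_seg)
  score <- rep(NA_real_, n_seg)
  line_used <- logical(lines$n)
  filled <- 0L
  for (i in ord) {
    s <- pair_seg[i]
    l <- pair_line[i]
    if (is.na(pick[s]) && !line_used[l]) {
      pick[s] <- l
      score[s] <- pair_score[i]
      line_used[l] <- TRUE
      filled <- filled + 1L
      if (filled == n_seg) break
    }
  }
  # branch pools exhausted: best unused line anywhere, best segments first
  open <- which(is.na(pick))
  if (length(open) > 0) {
    for (s in open) {
      cand <- which(!line_used)
      sc <- seg_score(s, cand)
      best <- order(sc, stats::runif(length(cand)), decreasing = TRUE)[1]
      pick[s] <- cand[best]
      score[s] <- sc[best]
      line_used[cand[best]] <- TRUE
    }
  }
  structure(list(H1 = lines$H1[pick, , drop = FALSE],
                 H2 = lines$H2[pick, , drop = FALSE],
                 assigned_segment = seq_len(n_seg),
                 line_index = pick, segment_index = score,
                 generation = lines$generation, map = map,
                 n = n_seg),
            class = c("il_population", "il_pop"))
}

# Candidate rows whose lineage branch (region system of the first
# selection) contains target segment `seg`; falls back to all lines when no
# branch information exists or the pool is empty.
branch_pool <- function(lines, map, seg) {
  all_rows <- seq_len(lines$n)
  kind <- lines$origin_kind %||% lines$branch_kind
  ids <- lines$origin %||% lines$branch
  if (is.null(kind) || kind == "none" || all(is.na(ids))) return(all_rows)
  spc <- map$segments_per_chrom
  chrom <- (seg - 1L) %/% spc + 1L
  seg_mid <- ((seg - 1L) %% spc + 0.5) * map$segment_length
  target <- switch(kind,
    chromosome = chrom,
    half = (chrom - 1L) * 2L + if (seg_mid < map$chrom_length / 2) 1L else 2L,
    segment = seg,
    NA_integer_)
  pool <- all_rows[!is.na(ids) & ids == target]
  if (length(pool) == 0) all_rows else pool
}

#' @export
print.il_population <- function(x, ...) {
  cat("<il_population> ", x$n, " introgression lines, generation ",
      x$generation, "\n", sep = "")
  invisible(x)
}
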