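#' Evaluation measures for an introgression-line population
#'
#' Nine measures characterise a final IL population. Carrier status is
#' presence-based (a heterozygous marker counts as carrying the donor
#' allele); donor genome *proportions* are dosage-based (a heterozygous
#' marker contributes 1/2).
#'
#' * `coverage()` — C_D, percent of markers at which at least one IL carries
#'   a donor allele.
#' * `coverage_depth()` — mean number of ILs carrying a donor allele,
#'   averaged over all marker loci (set `donor_loci_only = TRUE` to average
#'   over covered loci only).
#' * `disjunct_segments()` — N_D, the number of maximal genome intervals
#'   within which the joint genotype pattern of every haplotype of every IL
#'   is constant (per chromosome: distinct internal breakpoints + 1, summed
#'   over chromosomes).
#' * `resolution()` — R = total map length / N_D, in cM.
#' * `segment_stats()` — S_D, mean number of donor segments (maximal runs of
#'   donor-carrying markers) per IL, and L_D, the mean donor-segment length
#'   in cM (ILs without donor segments count 0 toward S_D and are excluded
#'   from the length mean).
#' * `donor_proportions()` — lambda_D (genome-wide), Z_C (carrier
#'   chromosome) and Z_S (assigned target segment) mean donor dosage, in
#'   percent.
#'
#' @param pop An `il_population` from [select_final_ils()] (any `il_pop`
#'   works for the measures that do not need segment assignments, given
#'   `map`).
#' @param map Genetic map; defaults to `pop$map`.
#' @param donor_loci_only Average depth over donor-covered loci only?
#' @return See each function; proportions are percentages.
#' @name measures
NULL

carrier_matrix <- function(pop) (pop$H1 | pop$H2)

#' @rdname measures
#' @export
coverage <- function(pop, map = pop$map) {
  100 * mean(colSums(carrier_matrix(pop)) > 0)
}

#' @rdname measures
#' @export
coverage_depth <- function(pop, map = pop$map, donor_loci_only = FALSE) {
  d <- colSums(carrier_matrix(pop))
  if (donor_loci_only) d <- d[d > 0]
  if (length(d) == 0) return(0)
  mean(d)
}

#' @rdname measures
#' @export
disjunct_segments <- function(pop, map = pop$map) {
  H <- rbind(pop$H1, pop$H2)
  cpp_pattern_intervals(H, map$n_chromosomes, map$markers_per_chrom)
}

#' @rdname measures
#' @export
resolution <- function(pop, map = pop$map) {
  map$total_length / disjunct_segments(pop, map)
}

#' @rdname measures
#' @export
segment_stats <- function(pop, map = pop$map) {
  C <- carrier_matrix(pop)
  mpc <- map$markers_per_chrom
  n <- nrow(C)
  # donor-segment starts: carrier marker whose left neighbour (within the
  # chromosome) is not a carrier
  starts <- matrix(0L, n, ncol(C))
  for (c in seq_len(map$n_chromosomes)) {
    off <- (c - 1L) * mpc
    block <- C[, off + seq_len(mpc), drop = FALSE]
    s <- block
    s[, -1] <- block[, -1] & !block[, -mpc]
    starts[, off + seq_len(mpc)] <- s
  }
  n_seg <- rowSums(starts)
  n_carrier <- rowSums(C)
  s_d <- mean(n_seg)
  has <- n_seg > 0
  l_d <- if (any(has))
    mean((n_carrier[has] * map$marker_spacing) / n_seg[has]) else NA_real_
  list(S_D = s_d, L_D = l_d)
}

#' @rdname measures
#' @export
donor_proportions <- function(pop, map = pop$map) {
  stopifnot(inherits(pop, "il_population"))
  lambda <- 100 * mean(donor_dosage(pop))
  segs <- region_partition(map, "segment")
  mpc <- map$markers_per_chrom
  zc <- zs <- numeric(pop$n)
  D <- pop$H1 + pop$H2
  for (i in seq_len(pop$n)) {
    s <- pop$assigned_segment[i]
    ch <- segs$chrom[s]
    chrom_cols <- (ch - 1L) * mpc + seq_len(mpc)
    zc[i] <- sum(D[i, chrom_cols]) / (2 * mpc)
    seg_cols <- segs$col_start[s]:segs$col_end[s]
    zs[i] <- sum(D[i, seg_cols]) / (2 * length(seg_cols))
  }
  list(lambda_D = lambda, Z_C = 100 * mean(zc), Z_S = 100 * mean(zs))
}

#' One-row measure report for an IL population
#'
#' Computes all nine measures plus the HT assay count, in the conventional
#' column order: C_D, depth, N_D, R, S_D, L_D, lambda_D, Z_C, Z_S, HT.
#'
#' @param pop An `il_population`.
#' @param ht HT assay count to report (e.g. `run$ht_total`).
#' @param map Genetic map; defaults to `pop$map`.
#' @return A one-row tibble.
#' @export
measure_report <- function(pop, ht = NA_integer_, map = pop$map) {
  tibble::as_tibble(measure_row(pop, ht, map))
}

# named list of all measures; tibble-free for use in replicate loops
measure_row <- function(pop, ht, map) {
  nd <- disjunct_segments(pop, map)
  ss <- segment_stats(pop, map)
  dp <- donor_proportions(pop, map)
  list(
    C_D = coverage(pop, map),
    depth = coverage_depth(pop, map),
    N_D = nd,
    R = map$total_length / nd,
    S_D = ss$S_D,
    L_D = ss$L_D,
    lambda_D = dp$lambda_D,
    Z_C = dp$Z_C,
    Z_S = dp$Z_S,
    HT = as.integer(ht)
  )
}

#' Graphical genotype matrix
#'
#' Haplotype-resolved genotype display: two rows per IL (one per haplotype)
#' over the marker grid, 1 = donor, 0 = recipient. For DH populations both
#' rows of an IL are identical; F3 populations may differ where residual
#' heterozygosity persists.
#'
#' @param pop An `il_population` (or any `il_pop`).
#' @param ils IL (row) indices to include; default all.
#' @param chroms Chromosome indices to include; default all.
#' @param map Genetic map; defaults to `pop$map`.
#' @return A tibble in long format: `il`, `haplotype`, `chrom`, `pos`,
#'   `allele` (`"donor"`/`"recipient"`).
#' @export
graphical_genotype <- function(pop, ils = seq_len(pop$n),
                               chroms = NULL, map = pop$map) {
  stopifnot(inherits(pop, "il_pop"))
  if (is.null(chroms)) chroms <- seq_len(map$n_chromosomes)
  keep <- map$chrom %in% chroms
  purrr::map_dfr(ils, function(i) {
    tibble::tibble(
      il = i,
      haplotype = rep(1:2, each = sum(keep)),
      chrom = rep(map$chrom[keep], 2),
      pos = rep(map$pos[keep], 2),
      allele = ifelse(c(pop$H1[i, keep], pop$H2[i, keep]) == 1L,
                      "donor", "recipient"))
  })
}
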