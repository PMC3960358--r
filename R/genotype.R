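#' Genotype populations
#'
#' A population is a pair of haplotype matrices (`H1`, `H2`, individuals in
#' rows, markers in columns; 1 = donor allele, 0 = recipient allele) plus a
#' generation label and, once region-based selection has occurred, the
#' selection-region "branch" each individual descends from. A single
#' genotype is a one-row population.
#'
#' @name il_pop
NULL

new_population <- function(H1, H2, map, generation,
                           branch_kind = "none",
                           branch = rep(NA_integer_, nrow(H1)),
                           origin_kind = "none",
                           origin = rep(NA_integer_, nrow(H1))) {
  stopifnot(is.matrix(H1), is.matrix(H2),
            identical(dim(H1), dim(H2)), ncol(H1) == map$n_markers,
            length(branch) == nrow(H1), length(origin) == nrow(H1))
  structure(list(H1 = H1, H2 = H2, generation = generation,
                 branch_kind = branch_kind, branch = as.integer(branch),
                 origin_kind = origin_kind, origin = as.integer(origin),
                 n = nrow(H1)),
            class = "il_pop")
}

#' @export
print.il_pop <- function(x, ...) {
  cat("<il_pop> ", x$n, " individual(s), generation ", x$generation,
      if (x$branch_kind != "none")
        paste0(", branches by ", x$branch_kind), "\n", sep = "")
  invisible(x)
}

#' Founder genotypes and the F1
#'
#' `founder_genotype()` creates fully homozygous donor or recipient parents;
#' `make_f1()` their hybrid, heterozygous (donor/recipient) at every marker.
#'
#' @param map An [il_map()].
#' @param type `"donor"` or `"recipient"`.
#' @param n Number of identical individuals to create.
#' @return An `il_pop`.
#' @export
founder_genotype <- function(map, type = c("donor", "recipient"), n = 1) {
  type <- match.arg(type)
  v <- if (type == "donor") 1L else 0L
  H <- matrix(v, nrow = n, ncol = map$n_markers)
  new_population(H, H, map, generation = type)
}

#' @rdname founder_genotype
#' @export
make_f1 <- function(map, n = 1) {
  new_population(matrix(1L, n, map$n_markers), matrix(0L, n, map$n_markers),
                 map, generation = "F1")
}

#' Simulate gametes from parent genotypes
#'
#' Meiosis follows the Haldane model: per chromosome, the number of
#' crossovers is Poisson with mean equal to the chromosome length in Morgans
#' (no interference, no obligate chiasma), crossover positions are uniform on
#' the chromosome, the starting parental strand is chosen with probability
#' 1/2, and the strand switches at each crossover. The expected
#' recombination fraction between markers d cM apart is Haldane's
#' r = (1 - exp(-2d/100)) / 2.
#'
#' @param pop An `il_pop` of parents.
#' @param map The [il_map()].
#' @param parents Integer vector of parent row indices, one gamete per entry
#'   (default: one gamete per parent, in order).
#' @return Integer matrix of gametes (rows) over markers (columns).
#' @export
simulate_gametes <- function(pop, map, parents = seq_len(pop$n)) {
  stopifnot(inherits(pop, "il_pop"), inherits(map, "il_map"))
  cpp_gametes(pop$H1, pop$H2, as.integer(parents), map$n_chromosomes,
              map$markers_per_chrom, map$chrom_length, map$pos_within)
}

#' Crossing, backcrossing, selfing and DH doubling
#'
#' `cross_populations()` draws one gamete from each parent per offspring.
#' `backcross()` crosses parents to the fully homozygous recipient; the
#' recipient gamete is the all-zero vector, so no meiosis is simulated on the
#' recipient side. `self_population()` unites two independent gametes of the
#' same parent. `make_dh()` simulates one gamete per parent and doubles it,
#' yielding a fully homozygous doubled-haploid line.
#'
#' @param mother,father,pop `il_pop` parent populations.
#' @param map The [il_map()].
#' @param mothers,fathers,parents Row indices selecting the parent of each
#'   offspring (recycled against each other where sensible).
#' @param generation Generation label for the offspring population.
#' @return An `il_pop` of offspring. Offspring inherit the branch label of
#'   their (non-recipient) parent.
#' @export
cross_populations <- function(mother, father, map,
                              mothers = seq_len(mother$n),
                              fathers = seq_len(father$n),
                              generation = "cross") {
  stopifnot(length(mothers) == length(fathers))
  g1 <- simulate_gametes(mother, map, mothers)
  g2 <- simulate_gametes(father, map, fathers)
  new_population(g1, g2, map, generation,
                 branch_kind = mother$branch_kind,
                 branch = mother$branch[mothers],
                 origin_kind = mother$origin_kind,
                 origin = mother$origin[mothers])
}

#' @rdname cross_populations
#' @export
backcross <- function(pop, map, parents = seq_len(pop$n),
                      generation = "BC") {
  g <- simulate_gametes(pop, map, parents)
  new_population(g, matrix(0L, nrow(g), ncol(g)), map, generation,
                 branch_kind = pop$branch_kind, branch = pop$branch[parents],
                 origin_kind = pop$origin_kind, origin = pop$origin[parents])
}

#' @rdname cross_populations
#' @export
self_population <- function(pop, map, parents = seq_len(pop$n),
                            generation = "self") {
  g <- cpp_self_gametes(pop$H1, pop$H2, as.integer(parents),
                        map$n_chromosomes, map$markers_per_chrom,
                        map$chrom_length, map$pos_within)
  new_population(g$H1, g$H2, map, generation,
                 branch_kind = pop$branch_kind, branch = pop$branch[parents],
                 origin_kind = pop$origin_kind, origin = pop$origin[parents])
}

#' @rdname cross_populations
#' @export
make_dh <- function(pop, map, parents = seq_len(pop$n), generation = "DH") {
  g <- simulate_gametes(pop, map, parents)
  new_population(g, g, map, generation,
                 branch_kind = pop$branch_kind, branch = pop$branch[parents],
                 origin_kind = pop$origin_kind, origin = pop$origin[parents])
}

#' Donor allele dosage
#'
#' Mean donor-allele dosage per individual over a marker set; a heterozygous
#' marker contributes 1/2. This is the "donor genome proportion" used by the
#' selection index and the population measures.
#'
#' @param pop An `il_pop`.
#' @param markers Marker (column) indices; default all markers.
#' @return Numeric vector, one proportion in `[0, 1]` per individual.
#' @export
donor_dosage <- function(pop, markers = NULL) {
  stopifnot(inherits(pop, "il_pop"))
  if (is.null(markers)) {
    (rowSums(pop$H1) + rowSums(pop$H2)) / (2 * ncol(pop$H1))
  } else {
    (rowSums(pop$H1[, markers, drop = FALSE]) +
       rowSums(pop$H2[, markers, drop = FALSE])) / (2 * length(markers))
  }
}

subset_population <- function(pop, idx, map, generation = pop$generation) {
  new_population(pop$H1[idx, , drop = FALSE], pop$H2[idx, , drop = FALSE],
                 map, generation, branch_kind = pop$branch_kind,
                 branch = pop$branch[idx],
                 origin_kind = pop$origin_kind, origin = pop$origin[idx])
}
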