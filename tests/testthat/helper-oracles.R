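# Brute-force oracles and toy-population builders. The oracles loop over
# markers and individuals naively and share no code with the implementation.

toy_map <- function(n_chrom = 1, len = 20, spacing = 1, seg = 20) {
  il_map(n_chrom, len, spacing, seg)
}

# population from explicit haplotype matrices
pop_from <- function(H1, H2, map, generation = "toy") {
  ilsim:::new_population(H1, H2, map, generation)
}

# an il_population with given haplotypes and segment assignment
ilpop_from <- function(H1, H2, map, assigned = seq_len(nrow(H1))) {
  structure(list(H1 = H1, H2 = H2, assigned_segment = assigned,
                 generation = "toy", map = map, n = nrow(H1)),
            class = c("il_population", "il_pop"))
}

# ideal library: IL i homozygous donor exactly on segment i
ideal_library <- function(map = il_map()) {
  n <- map$n_segments
  H <- matrix(0L, n, map$n_markers)
  for (i in seq_len(n)) H[i, map$segment == i] <- 1L
  ilpop_from(H, H, map)
}

recipient_library <- function(map = il_map()) {
  H <- matrix(0L, map$n_segments, map$n_markers)
  ilpop_from(H, H, map)
}

# random toy library on a small map; mixes homozygous and heterozygous donor
# stretches so all carrier/dosage paths are exercised
random_library <- function(map, n_il = 5, p_donor = 0.3, het = TRUE) {
  M <- map$n_markers
  H1 <- matrix(rbinom(n_il * M, 1, p_donor), n_il, M)
  H2 <- if (het) matrix(rbinom(n_il * M, 1, p_donor), n_il, M) else H1
  storage.mode(H1) <- "integer"; storage.mode(H2) <- "integer"
  ilpop_from(H1, H2, map, assigned = sample(map$n_segments, n_il,
                                            replace = n_il > map$n_segments))
}

oracle_coverage <- function(pop) {
  covered <- 0
  for (j in seq_len(ncol(pop$H1))) {
    if (any(pop$H1[, j] == 1 | pop$H2[, j] == 1)) covered <- covered + 1
  }
  100 * covered / ncol(pop$H1)
}

oracle_depth <- function(pop) {
  counts <- numeric(ncol(pop$H1))
  for (j in seq_len(ncol(pop$H1)))
    counts[j] <- sum(pop$H1[, j] == 1 | pop$H2[, j] == 1)
  mean(counts)
}

oracle_disjunct <- function(pop, map) {
  total <- 0
  for (c in seq_len(map$n_chromosomes)) {
    cols <- which(map$chrom == c)
    pat <- apply(rbind(pop$H1[, cols, drop = FALSE],
                       pop$H2[, cols, drop = FALSE]), 2, paste, collapse = "")
    total <- total + 1 + sum(pat[-1] != pat[-length(pat)])
  }
  total
}

oracle_segment_stats <- function(pop, map) {
  n_seg <- numeric(pop$n)
  mean_len <- numeric(pop$n)
  for (i in seq_len(pop$n)) {
    lens <- c()
    for (c in seq_len(map$n_chromosomes)) {
      cols <- which(map$chrom == c)
      carrier <- pop$H1[i, cols] == 1 | pop$H2[i, cols] == 1
      r <- rle(carrier)
      lens <- c(lens, r$lengths[r$values])
    }
    n_seg[i] <- length(lens)
    mean_len[i] <- if (length(lens)) mean(lens) * map$marker_spacing else NA
  }
  list(S_D = mean(n_seg),
       L_D = if (any(n_seg > 0)) mean(mean_len[n_seg > 0]) else NA_real_)
}

oracle_proportions <- function(pop, map) {
  d <- (pop$H1 + pop$H2) / 2
  lam <- mean(rowMeans(d))
  zc <- zs <- numeric(pop$n)
  for (i in seq_len(pop$n)) {
    s <- pop$assigned_segment[i]
    chrom_of_s <- map$chrom[match(s, map$segment)]
    zc[i] <- mean(d[i, map$chrom == chrom_of_s])
    zs[i] <- mean(d[i, map$segment == s])
  }
  list(lambda_D = 100 * lam, Z_C = 100 * mean(zc), Z_S = 100 * mean(zs))
}

# brute-force truncation selection for one region: full sort, take m
oracle_select <- function(pop, region, m) {
  idx <- selection_index(pop, region)
  order(idx, decreasing = TRUE)[seq_len(m)]
}

# Haldane mapping function
haldane_r <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2
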