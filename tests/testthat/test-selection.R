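map <- il_map()
regions_chr <- region_partition(map, "chromosome")

test_that("selection index realizes the donor/background trade-off", {
  # heterozygous donor across region 1, recipient elsewhere: 0.5 + 1.0
  H1 <- matrix(0L, 3, map$n_markers)
  H1[1, map$chrom == 1] <- 1L                 # het on chromosome 1
  H1[3, map$chrom == 1] <- 1L
  H2 <- matrix(0L, 3, map$n_markers)
  H2[3, map$chrom == 1] <- 1L                 # homozygous donor chromosome 1
  pop <- pop_from(H1, H2, map)
  idx <- selection_index(pop, regions_chr[1, ])
  expect_equal(idx[1], 1.5)
  expect_equal(idx[2], 1.0)   # all-recipient
  expect_equal(idx[3], 2.0)   # maximum: hom donor region, clean background
  expect_true(all(idx >= 0 & idx <= 2))
})

test_that("index weights are exposed for sensitivity analysis", {
  H1 <- matrix(0L, 1, map$n_markers)
  H1[1, map$chrom == 1] <- 1L
  pop <- pop_from(H1, H1, map)
  expect_equal(selection_index(pop, regions_chr[1, ], weights = c(2, 1)), 3)
  expect_equal(selection_index(pop, regions_chr[1, ], weights = c(0, 1)), 1)
})

test_that("per-region truncation matches a brute-force sort oracle", {
  set.seed(31)
  for (rep in 1:5) {
    pop <- pop_from(
      matrix(rbinom(40 * map$n_markers, 1, 0.2), 40),
      matrix(0L, 40, map$n_markers), map)
    regions <- region_partition(map, sample(c("chromosome", "half"), 1))
    m <- sample(1:4, 1)
    sel <- select_per_region(pop, regions, m)
    for (r in seq_len(nrow(regions))) {
      got <- sort(sel$individual[sel$region == r])
      want <- sort(oracle_select(pop, regions[r, ], m))
      # oracle ignores ties; scores at selected set must match exactly
      scores <- selection_index(pop, regions[r, ])
      expect_equal(sort(scores[got], decreasing = TRUE),
                   sort(scores[want], decreasing = TRUE))
    }
  }
})

test_that("selecting everyone returns the whole population for any region", {
  set.seed(32)
  pop <- pop_from(matrix(rbinom(10 * map$n_markers, 1, 0.2), 10),
                  matrix(0L, 10, map$n_markers), map)
  sel <- select_per_region(pop, regions_chr, m_per_region = 10)
  for (r in regions_chr$region)
    expect_setequal(sel$individual[sel$region == r], 1:10)
})

test_that("raising m never drops a previously selected individual", {
  set.seed(33)
  pop <- pop_from(matrix(rbinom(30 * map$n_markers, 1, 0.2), 30),
                  matrix(0L, 30, map$n_markers), map)
  for (m in 1:5) {
    set.seed(77)  # identical tie-break stream
    a <- select_per_region(pop, regions_chr, m)
    set.seed(77)
    b <- select_per_region(pop, regions_chr, m + 1)
    for (r in regions_chr$region)
      expect_true(all(a$individual[a$region == r] %in%
                        b$individual[b$region == r]))
  }
})

test_that("exact ties break reproducibly under a fixed seed", {
  H <- matrix(0L, 4, map$n_markers)
  H[1:2, map$chrom == 1] <- 1L   # two identical top scorers
  pop <- pop_from(H, H, map)
  set.seed(5)
  w1 <- select_per_region(pop, regions_chr[1, ], 1)$individual
  set.seed(5)
  w2 <- select_per_region(pop, regions_chr[1, ], 1)$individual
  expect_identical(w1, w2)
  expect_true(w1 %in% 1:2)
})

test_that("distinct selection assigns an individual to at most one region", {
  set.seed(34)
  # individual 1 is homozygous donor on chromosomes 1 and 2 and beats the
  # heterozygous carriers 2 and 3 for both regions; with distinct = TRUE
  # one region must take its runner-up
  H1 <- matrix(0L, 5, map$n_markers)
  H1[1, map$chrom %in% 1:2] <- 1L
  H1[2, map$chrom == 1] <- 1L
  H1[3, map$chrom == 2] <- 1L
  H2 <- matrix(0L, 5, map$n_markers)
  H2[1, map$chrom %in% 1:2] <- 1L
  pop <- pop_from(H1, H2, map)
  sel_free <- select_per_region(pop, regions_chr[1:2, ], 1, distinct = FALSE)
  expect_equal(sel_free$individual, c(1L, 1L))
  sel_dist <- select_per_region(pop, regions_chr[1:2, ], 1, distinct = TRUE)
  expect_equal(anyDuplicated(sel_dist$individual), 0L)
  expect_true(1L %in% sel_dist$individual)
  expect_true(all(sel_dist$individual[sel_dist$region == 1] %in% c(1L, 2L)))
  expect_true(all(sel_dist$individual[sel_dist$region == 2] %in% c(1L, 3L)))
})

test_that("final IL assembly picks the best distinct line per segment", {
  # ideal library: each line wins exactly its own segment, Z_S = 100
  lines <- ideal_library(map)
  lines$branch_kind <- "none"; lines$origin_kind <- "none"
  lines$branch <- lines$origin <- rep(NA_integer_, lines$n)
  set.seed(6)
  ils <- select_final_ils(lines, map)
  expect_equal(ils$line_index, 1:100)
  expect_equal(donor_proportions(ils)$Z_S, 100)

  # all-recipient lines: assignment still produced, Z_S = 0
  rec <- recipient_library(map)
  rec$branch_kind <- "none"; rec$origin_kind <- "none"
  rec$branch <- rec$origin <- rep(NA_integer_, rec$n)
  ils0 <- select_final_ils(rec, map)
  expect_equal(ils0$n, 100)
  expect_equal(donor_proportions(ils0)$Z_S, 0)
})

test_that("segment index ranks candidates by donor content and background", {
  # three candidates for segment 1: dosages (1.0, 0.5, 1.0) with background
  # recipient proportions (0.95, 0.99, 0.97) -> indices 1.95, 1.49, 1.97
  tm <- il_map(1, 120, 1, 20)   # 6 segments, 120 markers, 100 background
  n_bg <- 100
  mk_line <- function(seg_dosage, bg_recipient) {
    h1 <- h2 <- rep(0L, 120)
    if (seg_dosage >= 0.5) h1[1:20] <- 1L
    if (seg_dosage == 1.0) h2[1:20] <- 1L
    n_donor_bg <- round((1 - bg_recipient) * n_bg)
    if (n_donor_bg > 0) {
      h1[20 + seq_len(n_donor_bg)] <- 1L
      h2[20 + seq_len(n_donor_bg)] <- 1L
    }
    rbind(c(h1), c(h2))
  }
  specs <- list(c(1.0, 0.95), c(0.5, 0.99), c(1.0, 0.97))
  H <- lapply(specs, function(s) mk_line(s[1], s[2]))
  H1 <- do.call(rbind, lapply(H, function(x) x[1, , drop = FALSE]))
  H2 <- do.call(rbind, lapply(H, function(x) x[2, , drop = FALSE]))
  # pad with recipient lines so every segment can receive a distinct line
  H1 <- rbind(H1, matrix(0L, 4, 120)); H2 <- rbind(H2, matrix(0L, 4, 120))
  lines <- pop_from(H1, H2, tm)
  set.seed(8)
  ils <- select_final_ils(lines, tm)
  expect_equal(ils$line_index[1], 3L)             # the (1.0, 0.97) line
  expect_equal(ils$segment_index[1], 1.97, tolerance = 1e-12)
})
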