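map <- il_map()

test_that("gametes of homozygous parents copy the parental haplotype", {
  don <- founder_genotype(map, "donor")
  rec <- founder_genotype(map, "recipient")
  set.seed(1)
  expect_true(all(simulate_gametes(don, map, rep(1, 5)) == 1L))
  expect_true(all(simulate_gametes(rec, map, rep(1, 5)) == 0L))
})

test_that("no allele is created that a parent does not carry", {
  set.seed(42)
  f1 <- make_f1(map)
  bc1 <- backcross(f1, map, rep(1, 50), "BC1")
  bc2 <- backcross(bc1, map, seq_len(50), "BC2")
  # recipient-side haplotype all zero; every transmitted donor allele is
  # present in the parent at the same marker
  expect_true(all(bc2$H2 == 0L))
  carrier <- (bc1$H1 | bc1$H2)
  expect_true(all(bc2$H1 <= carrier))
  expect_true(all(bc2$H1 %in% c(0L, 1L)))
})

test_that("F1 gametes transmit donor alleles at frequency 1/2", {
  set.seed(7)
  n <- 20000
  g <- simulate_gametes(make_f1(map), map, rep(1, n))
  p <- mean(g)
  se <- sqrt(0.25 / (n * 10))   # per-chromosome strands are independent
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n) * sqrt(10)) # conservative
  expect_true(p > 0.45 && p < 0.55)
})

test_that("recombination follows Haldane's mapping function at 1-100 cM", {
  set.seed(11)
  n <- 40000
  g <- simulate_gametes(make_f1(map), map, rep(1, n))
  # marker pairs on chromosome 1: indices i and i+d (1 cM spacing)
  for (d in c(1, 10, 50, 100)) {
    a <- g[, 1]
    b <- g[, 1 + d]
    r_hat <- mean(a != b)
    r_exp <- haldane_r(d)
    se <- sqrt(r_exp * (1 - r_exp) / n)
    expect_lt(abs(r_hat - r_exp), 3 * se)
  }
})

test_that("crossing donor and recipient gives a fully heterozygous F1", {
  set.seed(2)
  off <- cross_populations(founder_genotype(map, "donor"),
                           founder_genotype(map, "recipient"), map,
                           mothers = rep(1, 3), fathers = rep(1, 3))
  expect_true(all(off$H1 == 1L))
  expect_true(all(off$H2 == 0L))
  rec2 <- cross_populations(founder_genotype(map, "recipient"),
                            founder_genotype(map, "recipient"), map)
  expect_true(all(rec2$H1 == 0L) && all(rec2$H2 == 0L))
})

test_that("mean donor dosage follows 2^-(t+1) over backcross generations", {
  set.seed(3)
  n <- 10000
  f1 <- make_f1(map)
  pop <- f1
  for (t in 1:3) {
    pop <- backcross(pop, map,
                     parents = rep(seq_len(pop$n), length.out = n),
                     generation = paste0("BC", t))
    d <- mean(donor_dosage(pop))
    expected <- 2^-(t + 1)
    # SE of the mean over n individuals; per-individual SD measured loosely
    se <- stats::sd(donor_dosage(pop)) / sqrt(n)
    expect_lt(abs(d - expected), 3 * se)
  }
})

test_that("selfing halves heterozygosity per generation (F3 at 1/4)", {
  set.seed(4)
  n <- 8000
  f1 <- make_f1(map)
  f2 <- self_population(f1, map, parents = rep(1, n), generation = "F2")
  f3 <- self_population(f2, map, generation = "F3")
  het2 <- mean(f2$H1 != f2$H2)
  het3 <- mean(f3$H1 != f3$H2)
  se2 <- stats::sd(rowMeans(f2$H1 != f2$H2)) / sqrt(n)
  se3 <- stats::sd(rowMeans(f3$H1 != f3$H2)) / sqrt(n)
  expect_lt(abs(het2 - 0.5), 3 * se2)
  expect_lt(abs(het3 - 0.25), 3 * se3)
  # allele frequency is preserved by selfing
  expect_lt(abs(mean((f2$H1 + f2$H2) / 2) - 0.5), 0.01)
})

test_that("doubled haploids are homozygous with the parental expectation", {
  set.seed(5)
  f1 <- make_f1(map)
  bc1 <- backcross(f1, map, rep(1, 2000), "BC1")
  bc2 <- backcross(bc1, map, rep(seq_len(2000), length.out = 4000), "BC2")
  dh <- make_dh(bc2, map)
  expect_identical(dh$H1, dh$H2)
  d <- donor_dosage(dh)
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.125), 3 * se)
  # DH of the F1 itself has expectation 1/2
  dhf1 <- make_dh(f1, map, parents = rep(1, 2000))
  expect_lt(abs(mean(donor_dosage(dhf1)) - 0.5), 0.02)
})

test_that("donor dosage counts heterozygous markers as one half", {
  expect_equal(donor_dosage(make_f1(map)), 0.5)
  expect_equal(donor_dosage(founder_genotype(map, "donor")), 1)
  tm <- toy_map()   # 20 markers, one segment
  H1 <- matrix(c(rep(1L, 10), rep(0L, 10)), 1)
  H2 <- matrix(0L, 1, 20)
  expect_equal(donor_dosage(pop_from(H1, H2, tm), 1:20), 0.25)
})

test_that("identical seeds give bit-identical gametes", {
  f1 <- make_f1(map)
  set.seed(99); g1 <- simulate_gametes(f1, map, rep(1, 100))
  set.seed(99); g2 <- simulate_gametes(f1, map, rep(1, 100))
  expect_identical(g1, g2)
})
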