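test_that("the catalogue holds all four series for both line methods", {
  cat_ <- scheme_catalogue()
  expect_equal(nrow(cat_), 32L)
  expect_equal(sum(cat_$line_method == "DH"), 16L)
  expect_equal(as.integer(table(cat_$series)[c("basic", "high_intensity",
                                              "final_selection", "increasing")]),
               c(10L, 6L, 12L, 4L))
  expect_error(builtin_scheme("no-such-scheme"), "unknown scheme")
})

test_that("HT accounting reproduces the published assay totals", {
  ht <- function(nm) ht_count(builtin_scheme(nm))
  expect_equal(ht("basic-bc2-dh-c"), 720L)
  expect_equal(ht("basic-bc2-f3-h"), 720L)
  expect_equal(ht("basic-bc3-dh-cc"), 1080L)
  expect_equal(ht("basic-bc3-f3-ch"), 1080L)
  expect_equal(ht("high-bc3-dh-hh"), 2160L)
  expect_equal(ht("high-bc3-f3-cc"), 2160L)
  expect_equal(ht("final-bc2-dh-cc"), 1440L)
  expect_equal(ht("final-bc2-f3-cc"), 1080L)
  # selfing saves exactly 360 assays over DH when selecting in the final BC
  expect_equal(ht("final-bc2-dh-hh") - ht("final-bc2-f3-hh"), 360L)
  expect_equal(ht("final-bc3-dh-ccc"), 1800L)
  expect_equal(ht("final-bc3-f3-hhh"), 1440L)
  expect_equal(ht("incr-bc3-dh-hhs"), 1440L)
  # a scheme genotyped only in the line generation costs exactly those assays
  cfg <- scheme_config("min", "basic", "DH", "", c(100, 100),
                       c(FALSE, FALSE), 100)
  expect_equal(ht_count(cfg), 100L)
})

test_that("scheme configuration rejects inconsistent strategies", {
  expect_error(scheme_config("x", "basic", "DH", "CX", c(360, 360),
                             c(TRUE, TRUE), 360), "letters")
  expect_error(scheme_config("x", "basic", "DH", "C", c(360, 360),
                             c(TRUE, TRUE), 360), "backcross generations")
})

test_that("a scheme run yields 100 ILs and a ledger matching ht_count", {
  for (nm in c("basic-bc2-dh-c", "final-bc2-f3-cc", "incr-bc3-dh-hhs")) {
    cfg <- builtin_scheme(nm)
    run <- run_scheme(cfg, seed = 101)
    expect_equal(run$ils$n, 100L)
    expect_equal(run$ht_total, ht_count(cfg))
    expect_equal(sum(run$ledger$n[run$ledger$genotyped]), run$ht_total)
    # each line serves at most one target segment
    expect_equal(anyDuplicated(run$ils$line_index), 0L)
  }
})

test_that("DH schemes give fully homozygous ILs, F3 schemes do not", {
  dh <- run_scheme(builtin_scheme("basic-bc2-dh-c"), seed = 102)
  expect_identical(dh$ils$H1, dh$ils$H2)
  f3 <- run_scheme(builtin_scheme("basic-bc2-f3-c"), seed = 103)
  expect_gt(mean(f3$ils$H1 != f3$ils$H2), 0)
})

test_that("branch count after BC1 selection equals the region count", {
  for (nm in c("basic-bc2-dh-c", "basic-bc2-dh-h")) {
    run <- run_scheme(builtin_scheme(nm), seed = 104, keep_lineage = TRUE)
    sel1 <- run$lineage[run$lineage$generation == "BC1-selected", ]
    n_regions <- if (grepl("-c$", nm)) 10L else 20L
    expect_equal(nrow(sel1), n_regions)
    expect_equal(sort(unique(sel1$branch)), seq_len(n_regions))
    # distinct individuals found the branches
    expect_equal(anyDuplicated(sel1$individual), 0L)
  }
})

test_that("runs replay bit-identically from the same seed", {
  cfg <- builtin_scheme("incr-bc3-f3-hhs")
  a <- run_scheme(cfg, seed = 105)
  b <- run_scheme(cfg, seed = 105)
  expect_identical(a$ils$H1, b$ils$H1)
  expect_identical(a$ils$H2, b$ils$H2)
  expect_identical(a$ils$line_index, b$ils$line_index)
})

test_that("schemes run on custom maps and scaled-down sizes", {
  tm <- il_map(2, 60, 1, 20)   # 6 target segments
  cfg <- scheme_config("toy", "basic", "DH", "C", c(24, 24),
                       c(TRUE, FALSE), 24)
  run <- run_scheme(cfg, map = tm, seed = 106)
  expect_equal(run$ils$n, 6L)
  expect_equal(run$ht_total, 48L)
  expect_identical(run$ils$H1, run$ils$H2)
})

test_that("scheme configurations load from YAML and JSON files", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("name: demo", "series: increasing", "line_method: F3",
               "strategy: HS", "bc_sizes: [40, 80]",
               "select_in: [yes, yes]", "lines_n: 40",
               "map: {chromosomes: 2, length_cM: 60, marker_spacing_cM: 1,",
               "      segment_cM: 20}"), f)
  cfg <- read_scheme_config(f)
  expect_equal(cfg$strategy, "HS")
  expect_equal(cfg$plans$size, c(40L, 80L))
  expect_equal(ht_count(cfg), 160L)
  m <- attr(cfg, "map")
  expect_equal(m$n_segments, 6L)
  run <- run_scheme(cfg, map = m, seed = 1)
  expect_equal(run$ils$n, 6L)
  unlink(f)

  g <- tempfile(fileext = ".json")
  writeLines(paste0('{"name":"demo2","line_method":"DH",',
    '"generations":[{"label":"BC1","size":40,"selection":"chromosome"},',
    '{"label":"BC2","size":40,"selection":"none"}],"lines_n":40}'), g)
  cfg2 <- read_scheme_config(g)
  expect_equal(cfg2$strategy, "C")
  expect_equal(cfg2$plans$selection, c("chromosome", "none"))
  expect_equal(ht_count(cfg2), 80L)
  unlink(g)
})
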