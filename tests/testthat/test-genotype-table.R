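test_that("genotype tables canonicalize calls and apply the missing sentinel", {
  gt <- tiny_table()
  expect_s3_class(gt, "genotype_table")
  expect_equal(gt_loci(gt), c("ms1", "ms2"))
  # pairs sorted ascending
  expect_true(all(gt$ms1.a1 <= gt$ms1.a2, na.rm = TRUE))
  # 0-coded call is missing on both columns
  expect_true(is.na(gt$ms2.a1[2]) && is.na(gt$ms2.a2[2]))
  # site referenced but absent from the site table is rejected
  expect_error(
    genotype_table(data.frame(individual_id = "x", site_id = 9L,
                              ms1.a1 = 1L, ms1.a2 = 1L),
                   sites = gt_sites(gt)),
    "site_id")
  expect_error(
    genotype_table(data.frame(individual_id = "x", site_id = 1L,
                              mito = "Q", ms1.a1 = 1L, ms1.a2 = 1L)),
    "mito")
})

test_that("CSV round trip is the identity", {
  gt <- tiny_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(gt, path, "csv")
  back <- read_genotype_table(path, "csv", sites = gt_sites(gt))
  expect_gt_equal(back, gt)
})

test_that("Genepop round trip preserves genotypes, sites and mitotypes", {
  gt <- tiny_table()
  path <- withr::local_tempfile(fileext = ".gen")
  write_genotype_table(gt, path, "genepop")
  back <- read_genotype_table(path, "genepop", sites = gt_sites(gt),
                              site_ids = c(1L, 2L))
  # genepop does not carry sex/year; compare the rest
  for (col in c("individual_id", "site_id", "mito",
                "ms1.a1", "ms1.a2", "ms2.a1", "ms2.a2")) {
    expect_equal(back[[col]], gt[[col]], info = col)
  }
})

test_that("empty table round-trips as a header-only CSV", {
  gt <- tiny_table()
  empty <- genotype_table(as.data.frame(gt)[0, , drop = FALSE],
                          loci = gt_loci(gt))
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(empty, path, "csv")
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_genotype_table(path, "csv")), 0L)
})

test_that("malformed Genepop input fails with the offending line", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("title", "locA", "POP", "ind1 ,  151155163"), path)
  expect_error(read_genotype_table(path, "genepop"), "line 4")
  writeLines(c("title", "locA", "locB", "POP", "ind1 ,  151155"), path)
  expect_error(read_genotype_table(path, "genepop"), "2 loci")
  expect_error(read_genotype_table(tempfile(), "csv"), "not found")
})

test_that("allele frequencies count copies and exclude missing calls", {
  gt <- one_locus_table(rbind(c(151L, 155L), c(151L, 151L)))
  af <- allele_frequencies(gt)
  expect_equal(af$freq[af$allele == "151"], 0.75)
  expect_equal(af$freq[af$allele == "155"], 0.25)
  expect_equal(unique(af$total), 4L)

  mono <- allele_frequencies(one_locus_table(rbind(c(7L, 7L), c(7L, 7L))))
  expect_equal(mono$freq, 1)

  # missing calls shrink the totals without dropping individuals
  gt2 <- one_locus_table(rbind(c(151L, 155L), c(0L, 0L)))
  af2 <- allele_frequencies(gt2)
  expect_equal(unique(af2$total), 2L)

  # group with zero typed individuals is flagged, not NaN
  af3 <- allele_frequencies(one_locus_table(rbind(c(0L, 0L))))
  expect_equal(nrow(af3), 0L)
  expect_equal(attr(af3, "empty_groups")$locus, "ms1")

  # frequencies sum to one per (group, locus)
  gt <- tiny_table()
  af <- allele_frequencies(gt)
  sums <- tapply(af$freq, paste(af$group, af$locus), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("frequency differentials: fixed difference, identity, antisymmetry", {
  gt <- tiny_table()
  d <- frequency_differential(gt, pool_a = 2L, pool_b = 1L)
  ms1 <- d[d$locus == "ms1", ]
  expect_equal(ms1$delta[ms1$allele == "163"], 0.75)
  expect_equal(sum(ms1$delta), 0, tolerance = 1e-12)
  expect_error(frequency_differential(gt, pool_a = 1:2, pool_b = 2L),
               "disjoint")

  # identical pools (same individuals duplicated at two sites) -> delta 0
  df <- as.data.frame(one_locus_table(rbind(c(1L, 2L), c(2L, 3L))))
  df2 <- df; df2$site_id <- 2L; df2$individual_id <- paste0(df2$individual_id, "b")
  both <- genotype_table(rbind(df, df2))
  d0 <- frequency_differential(both, pool_a = 2L, pool_b = 1L)
  expect_true(all(abs(d0$delta) < 1e-12))
  expect_equal(attr(d0, "summary")[["ms1"]], 0)

  # antisymmetry under pool swap
  d_ab <- frequency_differential(gt, pool_a = 2L, pool_b = 1L)
  d_ba <- frequency_differential(gt, pool_a = 1L, pool_b = 2L)
  expect_equal(d_ab$delta, -d_ba$delta)
})

test_that("diallelic reduction pools by differential sign", {
  # fixed difference: reduced frequency equals the pool-A allele frequency
  panel <- fixed_difference_panel(1L)
  sim <- simulate_parental_pools(panel, n_per_pool = 10, seed = 1)
  af <- allele_frequencies(sim$table)
  d <- frequency_differential(sim$table, pool_a = 2L, pool_b = 1L)
  red <- diallelic_reduction(af, d)
  red <- red[red$locus == "fd01", ]
  expect_equal(red$freq_a[red$group == "2"], 1)
  expect_equal(red$freq_a[red$group == "1"], 0)

  # brute-force pooling over a 4-allele toy equals the operation's output,
  # and the reduction preserves the per-locus summary differential
  gt <- one_locus_table(rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(4L, 4L)))
  df2 <- as.data.frame(one_locus_table(rbind(c(1L, 1L), c(3L, 4L), c(3L, 3L))))
  df2$site_id <- 2L; df2$individual_id <- paste0("b", seq_len(nrow(df2)))
  both <- genotype_table(rbind(as.data.frame(gt), df2))
  af <- allele_frequencies(both)
  d <- frequency_differential(both, pool_a = 2L, pool_b = 1L)
  red <- diallelic_reduction(af, d)
  for (g in c("1", "2")) {
    a_class <- d$allele[d$delta > 0]
    fg <- af[af$group == g, ]
    brute <- sum(fg$count[fg$allele %in% a_class]) /
      sum(fg$count[fg$allele %in% d$allele[d$delta != 0]])
    expect_equal(red$freq_a[red$group == g], brute)
  }
  # with no delta = 0 ties, the between-pool difference of reduced
  # frequencies equals the per-locus summary differential
  expect_equal(abs(diff(red$freq_a[match(c("2", "1"), red$group)])),
               sum(abs(d$delta)) / 2, tolerance = 1e-9)

  # a locus with all deltas zero is flagged non-informative
  same <- genotype_table(rbind(as.data.frame(one_locus_table(rbind(c(1L, 2L)))),
                               local({
                                 z <- as.data.frame(one_locus_table(rbind(c(1L, 2L))))
                                 z$site_id <- 2L; z$individual_id <- "z1"; z
                               })))
  af_s <- allele_frequencies(same)
  d_s <- frequency_differential(same, pool_a = 2L, pool_b = 1L)
  expect_error(diallelic_reduction(af_s, d_s), "non-informative")
})
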