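test_that("the generator is deterministic given its seed", {
  a <- simulate_hybrid_zone(hz_sim_config(seed = 101))
  b <- simulate_hybrid_zone(hz_sim_config(seed = 101))
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(a$truth$individuals, b$truth$individuals)
  c <- simulate_hybrid_zone(hz_sim_config(seed = 102))
  expect_false(identical(as.data.frame(a$table), as.data.frame(c$table)))
})

test_that("parental pools are in Hardy-Weinberg shape and share no alleles at
           fixed-difference loci", {
  sim <- simulate_parental_pools(fixed_difference_panel(5L),
                                 n_per_pool = 60, seed = 44)
  af <- allele_frequencies(sim$table)
  s_al <- af$allele[af$group == "1" & af$locus != "mtDNA"]
  n_al <- af$allele[af$group == "2" & af$locus != "mtDNA"]
  expect_length(intersect(s_al, n_al), 0L)
  expect_true(all(sim$table$mito[sim$table$site_id == 1L] == "S"))
  expect_true(all(sim$table$mito[sim$table$site_id == 2L] == "N"))

  # observed pool frequencies near their specification (binomial error)
  sim2 <- simulate_parental_pools(default_locus_panel(), n_per_pool = 80,
                                  seed = 45)
  af2 <- allele_frequencies(sim2$table)
  spec <- default_locus_panel()$ms05
  for (al in spec$alleles) {
    obs <- af2$freq[af2$group == "1" & af2$locus == "ms05" & af2$allele == al]
    obs <- if (length(obs)) obs else 0
    p <- spec$s[[al]]
    expect_lt(abs(obs - p), 4 * sqrt(p * (1 - p) / 160) + 0.01)
  }
})

test_that("genotype classes have the defined gamete structure", {
  sites <- data.frame(site_id = 1:3, name = c("a", "b", "c"),
                      distance_km = c(0, 10, 20), lat = NA, lon = NA, n = 60)
  w <- matrix(0, 3, 6, dimnames = list(NULL,
    c("P_S", "P_N", "F1", "F2", "BC_S", "BC_N")))
  w[1, "F1"] <- 1; w[2, "BC_N"] <- 1; w[3, "F2"] <- 1
  sim <- simulate_hybrid_zone(hz_sim_config(fixed_difference_panel(20L),
                                            sites, ancestry = w, seed = 51))
  gt <- sim$table
  # F1: heterozygous at every fixed-difference locus
  f1 <- gt[gt$site_id == 1L, ]
  for (loc in gt_loci(gt)[1:5])
    expect_true(all(f1[[paste0(loc, ".a1")]] == 151L &
                    f1[[paste0(loc, ".a2")]] == 163L))
  # BC_N: expected northern dose 0.75 per locus, within 3 binomial SE
  bc <- gt[gt$site_id == 2L, ]
  doses <- unlist(lapply(gt_loci(gt), function(loc)
    (bc[[paste0(loc, ".a1")]] == 163L) + (bc[[paste0(loc, ".a2")]] == 163L)))
  n_cop <- length(doses) * 2
  expect_lt(abs(mean(doses) / 2 - 0.75), 3 * sqrt(0.75 * 0.25 / n_cop) + 0.01)
  # F2: dose 0.5 and ~half heterozygous
  f2 <- gt[gt$site_id == 3L, ]
  d2 <- unlist(lapply(gt_loci(gt), function(loc)
    (f2[[paste0(loc, ".a1")]] == 163L) + (f2[[paste0(loc, ".a2")]] == 163L)))
  expect_lt(abs(mean(d2) / 2 - 0.5), 0.05)
  expect_lt(abs(mean(d2 == 1L) - 0.5), 0.06)
})

test_that("clinal regime reproduces the ancestry cline site by site", {
  cl <- cline_model(centre = 1217, width = 58)
  cfg <- hz_sim_config(fixed_difference_panel(9L), killifish_transect(),
                       ancestry = cl, seed = 61)
  sim <- simulate_hybrid_zone(cfg)
  af <- allele_frequencies(sim$table)
  sites <- killifish_transect()
  for (sid in c(1L, 4L, 8L, 13L)) {
    p <- cline_eval(cl, sites$distance_km[sites$site_id == sid])
    nn <- 2 * sites$n[sites$site_id == sid] * 9
    obs <- af[af$group == as.character(sid) & af$locus != "mtDNA" &
                af$allele == "163", ]
    phat <- sum(obs$count) / (2 * sites$n[sites$site_id == sid] * 9)
    expect_lt(abs(phat - p), 4 * sqrt(max(p * (1 - p), 0.01) / nn) + 0.02)
  }
  # truth table mirrors cline_eval
  tf <- sim$truth$site_freqs
  expect_equal(tf$h_expected[tf$site_id == 4L][1],
               cline_eval(cl, sites$distance_km[4]))
})

test_that("simulated counts feed straight back into cline fitting", {
  d <- simulate_clinal_counts(cline_model(1200, 60, 0, 1),
                              data.frame(distance = killifish_transect()$distance_km,
                                         total = 50), seed = 71)
  expect_true(all(d$successes >= 0 & d$successes <= d$total))
  # deterministic end sites
  d0 <- simulate_clinal_counts(cline_model(1200, 60, 0, 1),
                               data.frame(distance = c(0, 2400), total = 30),
                               seed = 72)
  expect_equal(d0$successes, c(0L, 30L))
  expect_error(simulate_clinal_counts(cline_model(1200, 60),
                                      data.frame(distance = 1, total = 0)),
               "positive")
})

test_that("simulator output round-trips through the file formats", {
  sim <- simulate_hybrid_zone(preset_bimodal_config(n = 30, seed = 81))
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(sim$table, path, "csv")
  back <- read_genotype_table(path, "csv", sites = gt_sites(sim$table))
  expect_gt_equal(back, sim$table)
  pathg <- withr::local_tempfile(fileext = ".gen")
  write_genotype_table(sim$table, pathg, "genepop")
  backg <- read_genotype_table(pathg, "genepop",
                               site_ids = unique(sim$table$site_id))
  expect_equal(nrow(backg), 30L)
})

test_that("invalid configurations are rejected", {
  expect_error(hz_sim_config(ancestry = c(P_S = 0.6, P_N = 0.6)), "sum to 1")
  expect_error(hz_sim_config(ancestry = c(P_S = 1.4, P_N = -0.4)),
               "nonnegative")
  expect_error(hz_sim_config(ancestry = c(WILD = 1)), "named")
  expect_error(locus_spec("x", c(`1` = 0.5), c(`2` = 1)), "sum to 1")
  st <- killifish_transect(); st$n <- NA
  expect_error(hz_sim_config(sites = st), "sample sizes")
})
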