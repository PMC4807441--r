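pf_from_freqs <- function(freq_list, pool_n = c(A = 60, B = 60)) {
  # freq_list: per locus list(S = named freqs, N = named freqs)
  out <- lapply(freq_list, function(f) {
    alleles <- sort(unique(c(names(f$S), names(f$N))))
    m <- rbind(S = rep(0, length(alleles)), N = rep(0, length(alleles)))
    colnames(m) <- alleles
    m["S", names(f$S)] <- f$S; m["N", names(f$N)] <- f$N
    m
  })
  structure(out, pool_n = lapply(out, function(x) pool_n),
            class = "parental_freqs")
}

gt_single <- function(calls) {
  df <- data.frame(individual_id = "x", site_id = 1L, stringsAsFactors = FALSE)
  for (loc in names(calls)) {
    df[[paste0(loc, ".a1")]] <- calls[[loc]][1L]
    df[[paste0(loc, ".a2")]] <- calls[[loc]][2L]
  }
  genotype_table(df)
}

test_that("fixed-difference boundaries: pure and F1 individuals", {
  fl <- lapply(setNames(1:5, paste0("L", 1:5)), function(i)
    list(S = c(`151` = 1), N = c(`163` = 1)))
  pf <- pf_from_freqs(fl)
  pure_n <- gt_single(setNames(rep(list(c(163L, 163L)), 5), paste0("L", 1:5)))
  expect_equal(hybrid_index(pure_n, pf)$h, 1)
  pure_s <- gt_single(setNames(rep(list(c(151L, 151L)), 5), paste0("L", 1:5)))
  expect_equal(hybrid_index(pure_s, pf)$h, 0)
  f1 <- gt_single(setNames(rep(list(c(151L, 163L)), 5), paste0("L", 1:5)))
  res <- hybrid_index(f1, pf)
  expect_equal(res$h, 0.5, tolerance = 1e-6)   # [h(1-h)]^L peaks at 1/2
  expect_equal(res$n_loci, 5L)
})

test_that("the estimate matches a brute-force grid over random frequencies", {
  set.seed(14)
  for (rep in 1:12) {
    fl <- lapply(setNames(1:3, paste0("L", 1:3)), function(i) {
      s <- runif(3); n <- runif(3)
      list(S = setNames(s / sum(s), c("1", "2", "3")),
           N = setNames(n / sum(n), c("1", "2", "3")))
    })
    pf <- pf_from_freqs(fl)
    calls <- lapply(setNames(1:3, paste0("L", 1:3)),
                    function(i) sample(1:3, 2, TRUE))
    gt <- gt_single(calls)
    mine <- hybrid_index(gt, pf)$h
    pN <- unlist(lapply(names(calls), function(l)
      fl[[l]]$N[as.character(calls[[l]])]))
    pS <- unlist(lapply(names(calls), function(l)
      fl[[l]]$S[as.character(calls[[l]])]))
    expect_lt(abs(mine - oracle_hybrid_index(pN, pS)), 1e-3)
  }
})

test_that("swapping the parental pools maps h to 1 - h", {
  sim <- simulate_hybrid_zone(hz_sim_config(seed = 19))
  sub <- gt_subset_sites(sim$table, c(1L, 4L, 13L))
  a <- hybrid_index(sub, parental_frequencies(sub, 1L, 13L))
  b <- hybrid_index(sub, parental_frequencies(sub, 13L, 1L))
  ok <- !is.na(a$h)
  expect_lt(max(abs(a$h[ok] - (1 - b$h[ok]))), 1e-4)
})

test_that("adding a homozygous-northern diagnostic locus never lowers h", {
  set.seed(25)
  for (rep in 1:8) {
    fl <- lapply(setNames(1:3, paste0("L", 1:3)), function(i) {
      s <- runif(2); n <- runif(2)
      list(S = setNames(s / sum(s), c("1", "2")),
           N = setNames(n / sum(n), c("1", "2")))
    })
    calls <- lapply(setNames(1:3, paste0("L", 1:3)),
                    function(i) sample(1:2, 2, TRUE))
    h0 <- hybrid_index(gt_single(calls), pf_from_freqs(fl))$h
    fl$L4 <- list(S = c(`151` = 1), N = c(`163` = 1))
    calls$L4 <- c(163L, 163L)
    h1 <- hybrid_index(gt_single(calls), pf_from_freqs(fl))$h
    expect_gte(h1, h0 - 1e-9)
  }
})

test_that("simulated genotype classes recover their expected ancestry", {
  sites <- data.frame(site_id = 1:4, name = c("ps", "f1", "bc", "pn"),
                      distance_km = c(0, 10, 20, 30), lat = NA, lon = NA,
                      n = 40)
  w <- matrix(0, 4, 6, dimnames = list(NULL,
    c("P_S", "P_N", "F1", "F2", "BC_S", "BC_N")))
  w[1, "P_S"] <- 1; w[2, "F1"] <- 1; w[3, "BC_N"] <- 1; w[4, "P_N"] <- 1
  sim <- simulate_hybrid_zone(hz_sim_config(fixed_difference_panel(20L),
                                            sites, ancestry = w, seed = 23))
  pf <- pf_from_freqs(lapply(
    setNames(names(fixed_difference_panel(20L)), names(fixed_difference_panel(20L))),
    function(l) list(S = c(`151` = 1), N = c(`163` = 1))))
  hi <- hybrid_index(sim$table, pf)
  means <- tapply(hi$h, hi$site_id, mean)
  expect_lt(abs(means[["1"]] - 0), 0.03)
  expect_lt(abs(means[["2"]] - 0.5), 0.03)
  expect_lt(abs(means[["3"]] - 0.75), 0.03)
  expect_lt(abs(means[["4"]] - 1), 0.03)
  # support intervals contain the estimate
  expect_true(all(hi$lo <= hi$h + 1e-9 & hi$h <= hi$hi + 1e-9))
})

test_that("an individual with no usable loci is flagged, not guessed", {
  fl <- list(L1 = list(S = c(`151` = 1), N = c(`163` = 1)))
  gt <- gt_single(list(L1 = c(999L, 999L)))  # allele unseen in both pools
  res <- hybrid_index(gt, pf_from_freqs(fl))
  expect_true(is.na(res$h))
  expect_equal(attr(res, "excluded"), "x")
})

test_that("histogram bins are left-closed with a closed final bin", {
  counts <- hybrid_index_distribution(c(0.05, 0.95, 1.0))
  expect_equal(as.integer(counts), c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 2L))
  expect_equal(sum(hybrid_index_distribution(seq(0.005, 0.995, by = 0.01))),
               100L)
  expect_equal(as.integer(hybrid_index_distribution(seq(0.005, 0.995, by = 0.01))),
               rep(10L, 10L))
  expect_length(hybrid_index_distribution(numeric(0)), 0L)
  expect_warning(hybrid_index_distribution(c(0.5, NA)), "missing")
  expect_error(hybrid_index_distribution(c(-0.1, 0.5)), "0, 1")

  # bimodal class mixture dominates the two end bins
  sim <- simulate_hybrid_zone(preset_bimodal_config(n = 89, seed = 3))
  panel <- fixed_difference_panel(9L)
  pf <- pf_from_freqs(lapply(setNames(names(panel), names(panel)),
                             function(l) list(S = c(`151` = 1),
                                              N = c(`163` = 1))))
  counts <- hybrid_index_distribution(hybrid_index(sim$table, pf))
  expect_gt(counts[1] + counts[10], sum(counts[2:9]))
})
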