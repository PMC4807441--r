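test_that("k = 1 gives unit memberships and pooled frequencies", {
  sim <- simulate_parental_pools(default_locus_panel()[1:4],
                                 n_per_pool = 10, seed = 1)
  fit <- admixture_em(sim$table, k = 1, seed = 2)
  expect_true(all(abs(fit$q - 1) < 1e-12))
  af <- allele_frequencies(sim$table, groups = list(all = 1:2),
                           include_mito = FALSE)
  f1 <- af[af$locus == "ms01", ]
  expect_equal(as.numeric(fit$freqs$ms01[1, as.character(f1$allele)]),
               f1$freq, tolerance = 1e-6)
})

test_that("EM separates unadmixed pools and places F1s at one half", {
  panel <- fixed_difference_panel(9L)
  sim <- simulate_parental_pools(panel, n_per_pool = 30, seed = 5)
  fit <- admixture_em(sim$table, k = 2, seed = 6)
  truth <- ifelse(sim$table$site_id == 2L, 1, 0)
  expect_lt(max(abs(fit$q[, 2L] - truth)), 0.02)
  # EM log-likelihood is non-decreasing
  expect_true(all(diff(fit$ll_trace) > -1e-8))
  expect_true(fit$converged)

  # add F1s at a middle site
  sites <- data.frame(site_id = 1:3, name = c("s", "mid", "n"),
                      distance_km = c(0, 800, 1631), lat = NA, lon = NA,
                      n = c(30, 20, 30))
  w <- matrix(0, 3, 6, dimnames = list(NULL,
    c("P_S", "P_N", "F1", "F2", "BC_S", "BC_N")))
  w[1, "P_S"] <- 1; w[3, "P_N"] <- 1; w[2, "F1"] <- 1
  sim2 <- simulate_hybrid_zone(hz_sim_config(panel, sites, ancestry = w,
                                             seed = 8))
  fit2 <- admixture_em(sim2$table, k = 2, seed = 9)
  f1q <- fit2$q[sim2$table$site_id == 2L, 2L]
  expect_lt(max(abs(f1q - 0.5)), 0.05)
})

test_that("memberships are stable under permutation of individuals", {
  panel <- fixed_difference_panel(6L)
  sim <- simulate_parental_pools(panel, n_per_pool = 20, seed = 3)
  fit <- admixture_em(sim$table, k = 2, seed = 4)
  df <- as.data.frame(sim$table)
  set.seed(11); df <- df[sample.int(nrow(df)), ]
  gt2 <- genotype_table(df, loci = gt_loci(sim$table), sites = gt_sites(sim$table))
  fit2 <- admixture_em(gt2, k = 2, seed = 4)
  expect_lt(max(abs(fit$q[rownames(fit2$q), 2L] - fit2$q[, 2L])), 1e-3)
})

test_that("Evanno delta-K: arithmetic, zero curvature, simulated peak at 2", {
  logl <- list(`1` = c(-100, -101, -99), `2` = c(-50, -51, -49),
               `3` = c(-48, -49, -47), `4` = c(-47, -48, -46))
  ev <- evanno_delta_k(logl)
  expect_equal(ev$delta_k[2], abs(-48 - 2 * (-50) + (-100)) / sd(c(-50, -51, -49)))
  expect_equal(attr(ev, "suggested_k"), 2L)
  expect_true(is.na(ev$delta_k[1]) && is.na(ev$delta_k[4]))

  # linear mean log-likelihood: all interior delta-k are zero
  lin <- list(`1` = c(-30, -31, -29), `2` = c(-20, -21, -19),
              `3` = c(-10, -11, -9))
  expect_equal(evanno_delta_k(lin)$delta_k[2], 0)

  expect_error(evanno_delta_k(logl[c(1, 3)]), "consecutive")
  expect_error(evanno_delta_k(list(`1` = c(-1, -2), `2` = c(-1, -2),
                                   `3` = c(-1, -2))), "replicates")

  # two-gene-pool data: the log-likelihood gain collapses after k = 2 (the
  # curvature underlying delta-K peaks there); with the point-estimating EM
  # replicates can agree exactly, in which case delta-K itself is flagged NA
  sites3 <- data.frame(site_id = 1:3, name = c("s", "mid", "n"),
                       distance_km = c(0, 800, 1631), lat = NA, lon = NA,
                       n = c(15, 10, 15))
  w3 <- matrix(0, 3, 6, dimnames = list(NULL,
    c("P_S", "P_N", "F1", "F2", "BC_S", "BC_N")))
  w3[1, "P_S"] <- 1; w3[2, "F1"] <- 1; w3[3, "P_N"] <- 1
  sim <- simulate_hybrid_zone(hz_sim_config(fixed_difference_panel(6L),
                                            sites3, ancestry = w3, seed = 13))
  reps <- admixture_replicates(sim$table, k_range = 1:3, n_rep = 3, seed = 17)
  ev2 <- evanno_delta_k(reps$logl)
  gains <- diff(ev2$mean_logl)
  expect_gt(gains[1], 10 * max(gains[2], 1))
  if (!is.na(attr(ev2, "suggested_k")))
    expect_equal(attr(ev2, "suggested_k"), 2L)
})

test_that("parental-site rule finds the innermost parental sites", {
  sites <- data.frame(site_id = 1:7, name = letters[1:7],
                      distance_km = seq(0, 600, 100), lat = NA, lon = NA, n = 10)
  qbar <- c(0.02, 0.05, 0.3, 0.5, 0.7, 0.95, 0.97)
  set.seed(2)
  q <- unlist(lapply(qbar, function(m) pmin(pmax(rnorm(10, m, 0.02), 0), 1)))
  sid <- rep(1:7, each = 10)
  res <- select_parental_sites(q, sid, sites)
  expect_equal(res$southern, 2L)
  expect_equal(res$northern, 6L)

  # all sites admixed: no parental flank
  q_adm <- runif(70, 0.3, 0.7)
  expect_error(select_parental_sites(q_adm, sid, sites), "manually")
})
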