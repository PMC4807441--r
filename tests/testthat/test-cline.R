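test_that("cline evaluation: midpoint, limits, and the published mtDNA shape", {
  m <- cline_model(centre = 300, width = 80, p_min = 0.1, p_max = 0.9)
  expect_equal(cline_eval(m, 300), 0.5)           # (p_min + p_max) / 2
  m01 <- cline_model(300, 80, 0, 1)
  expect_equal(cline_eval(m01, -1e6), 0, tolerance = 1e-12)
  expect_equal(cline_eval(m01, 1e6), 1, tolerance = 1e-12)
  # steep mitochondrial cline: frequency at its own centre is the midpoint
  mt <- cline_model(centre = 1217.47, width = 57.89, p_min = 0, p_max = 0.98)
  expect_equal(round(cline_eval(mt, 1217.47), 2), 0.49)
  expect_error(cline_model(0, -5), "width")
})

test_that("cline evaluation is strictly monotone, tails included", {
  xs <- seq(900, 1500, by = 2.5)
  for (m in list(cline_model(1200, 60, 0.05, 0.95),
                 cline_model(1200, 60, 0.05, 0.95, variant = "III",
                             delta_l = 40, tau_l = 0.4,
                             delta_r = 70, tau_r = 0.8))) {
    p <- cline_eval(m, xs)
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 0 & p <= 1))
  }
  # tails are continuous at the splice points
  m3 <- cline_model(1200, 60, 0, 1, variant = "III",
                    delta_l = 35, tau_l = 0.3, delta_r = 50, tau_r = 0.6)
  eps <- 1e-9
  expect_equal(cline_eval(m3, 1165 - eps), cline_eval(m3, 1165 + eps),
               tolerance = 1e-6)
  expect_equal(cline_eval(m3, 1250 - eps), cline_eval(m3, 1250 + eps),
               tolerance = 1e-6)
})

test_that("binomial log-likelihood matches a hand-summed toy", {
  m <- cline_model(100, 50, 0.1, 0.8)
  d <- data.frame(distance = c(50, 100, 150), successes = c(3, 10, 17),
                  total = c(20, 20, 20))
  p <- cline_eval(m, d$distance)
  expect_equal(cline_loglik(m, d),
               sum(d$successes * log(p) + (20 - d$successes) * log(1 - p)),
               tolerance = 1e-9)
  # flat model on balanced data
  flat <- fit_cline(data.frame(distance = c(0, 50, 100),
                               successes = c(10, 10, 10), total = 20), "null")
  expect_equal(flat$logLik, 60 * log(0.5), tolerance = 1e-9)
  expect_equal(flat$k, 1L)
  # a model predicting the observed proportions maximizes the likelihood
  sat <- cline_model(100, 50, p_min = 3 / 20, p_max = 17 / 20)
  expect_gte(cline_loglik(sat, d) + 1e-9,
             cline_loglik(cline_model(100, 80, 0.1, 0.8), d))
  expect_error(cline_loglik(m, data.frame(distance = c(0, Inf),
                                          successes = 0:1, total = 2)),
               "finite")
})

test_that("fit_cline recovers simulated parameters and orders the ends", {
  truth <- cline_model(1200, 60, 0, 1)
  sites <- killifish_transect()
  d <- simulate_clinal_counts(truth, data.frame(distance = sites$distance_km,
                                                total = 100), seed = 21)
  fit <- fit_cline(d, "II", seed = 1)
  expect_lt(abs(fit$model$centre - 1200), 25)
  expect_lt(abs(fit$model$width - 60), 60)
  expect_lte(fit$model$p_min, fit$model$p_max)
  expect_true(fit$converged)
  ci <- confint(fit, parm = c("centre", "width"))
  expect_true(ci["centre", 1] <= fit$model$centre &&
              fit$model$centre <= ci["centre", 2])
  expect_true(ci["centre", 1] <= 1200 && 1200 <= ci["centre", 2])

  # deterministic given the seed
  fit2 <- fit_cline(d, "II", seed = 1)
  expect_identical(coef(fit), coef(fit2))

  expect_error(fit_cline(d[1:2, ], "II"), "3 sites")
})

test_that("fit methods: predict, residuals, simulate, logLik/AIC", {
  d <- simulate_clinal_counts(cline_model(300, 80, 0, 1),
                              data.frame(distance = seq(0, 600, 60),
                                         total = 80), seed = 3)
  fit <- fit_cline(d, "II", seed = 2)
  expect_equal(predict(fit, c(300)), cline_eval(fit$model, 300))
  expect_equal(length(residuals(fit)), nrow(d))
  expect_equal(AIC(fit), fit$aic)
  sim <- simulate(fit, nsim = 2, seed = 4)
  expect_true(all(sim$sim_1 <= sim$total))
  sim_b <- simulate(fit, nsim = 2, seed = 4)
  expect_identical(sim, sim_b)
})

test_that("variant I fixes the ends and null fits a flat line", {
  d <- data.frame(distance = c(0, 100, 200, 300), successes = c(1, 5, 15, 19),
                  total = 20)
  f1 <- fit_cline(d, "I", fixed_ends = c(0.05, 0.95), seed = 1)
  expect_equal(f1$model$p_min, 0.05)
  expect_equal(f1$model$p_max, 0.95)
  expect_equal(f1$k, 2L)
  fn <- fit_cline(d, "null")
  expect_equal(fn$model$p_min, sum(d$successes) / sum(d$total))
})

test_that("AIC selection picks the lowest with ties to fewer parameters", {
  expect_equal(
    as.character(select_cline_model(c(null = 26.395, I = 21.223,
                                      II = 15.922, III = 24.875))), "II")
  expect_equal(
    as.character(select_cline_model(c(null = 104.387, I = 11.734,
                                      II = 15.031, III = 22.600))), "I")
  expect_equal(as.character(select_cline_model(c(II = 10, III = 10))), "II")
  expect_error(select_cline_model(numeric(0)), "no fitted")
  expect_error(select_cline_model(c(II = 10)), "two")
})

test_that("support intervals: closed-form quadratic and brute-force grid", {
  # logL = -(theta - 3)^2 drops 2 units at 3 +- sqrt(2)
  f <- function(th) -(th - 3)^2
  ci <- support_interval(f, mle = 3, lower = -10, upper = 10)
  expect_equal(as.numeric(ci), c(3 - sqrt(2), 3 + sqrt(2)), tolerance = 1e-5)
  expect_false(any(attr(ci, "clipped")))

  # clipped at the bound
  ci2 <- support_interval(f, mle = 3, lower = 2.5, upper = 10)
  expect_equal(unname(ci2[1]), 2.5)
  expect_true(attr(ci2, "clipped")[["lower"]])

  # profile endpoints agree with a fine brute-force grid scan
  d <- simulate_clinal_counts(cline_model(300, 80, 0, 1),
                              data.frame(distance = seq(0, 600, 50),
                                         total = 60), seed = 9)
  fit <- fit_cline(d, "II", seed = 2)
  ci <- confint(fit, "centre")
  grid <- seq(ci["centre", 1] - 15, ci["centre", 2] + 15, by = 0.5)
  prof <- vapply(grid, function(v) {
    opt <- optim(c(log(fit$model$width),
                   fit$model$p_min,
                   max(min((fit$model$p_max - fit$model$p_min) /
                             max(1 - fit$model$p_min, 1e-9), 1), 0)),
      function(par) {
        m <- par[2]
        -cline_loglik(cline_model(v, exp(par[1]), m, m + (1 - m) * par[3]), d)
      }, method = "L-BFGS-B", lower = c(log(1), 0, 0),
      upper = c(log(3000), 1, 1))
    -opt$value
  }, 0)
  inside <- grid[prof >= fit$logLik - 2]
  expect_lt(abs(min(inside) - ci["centre", 1]), 1)
  expect_lt(abs(max(inside) - ci["centre", 2]), 1)
})

test_that("neutral width closed form and inversion", {
  expect_equal(signif(neutral_cline_width(15000, 2), 3), 614)
  expect_equal(neutral_cline_width(1, 1), sqrt(2 * pi), tolerance = 1e-12)
  set.seed(6)
  for (i in 1:20) {
    T <- runif(1, 1, 1e5); s <- runif(1, 0.1, 10)
    expect_equal(time_since_contact(neutral_cline_width(T, s), s), T,
                 tolerance = 1e-9)
  }
  expect_error(neutral_cline_width(-1, 2), "positive")
  expect_error(time_since_contact(0, 2), "positive")
})

test_that("cline_data builds per-site counts from genotype tables", {
  sim <- simulate_hybrid_zone(hz_sim_config(seed = 33))
  diffs <- frequency_differential(sim$table, pool_a = 13L, pool_b = 1L)
  d_mt <- cline_data(sim$table, "mtDNA")
  expect_equal(nrow(d_mt), 13L)
  expect_true(all(diff(d_mt$distance) > 0))
  d_ms <- cline_data(sim$table, "ms01", diffs)
  expect_true(all(d_ms$successes <= d_ms$total))
  # northern-composite frequency rises with distance
  expect_gt(mean(tail(d_ms$successes / d_ms$total, 3)),
            mean(head(d_ms$successes / d_ms$total, 3)))

  # sex-stratified input uses only the requested individuals
  df <- as.data.frame(sim$table)
  df$sex <- rep(c("F", "M"), length.out = nrow(df))
  gts <- genotype_table(df, loci = gt_loci(sim$table),
                        sites = gt_sites(sim$table))
  d_f <- cline_data(gts, "mtDNA", sex = "F")
  d_all <- cline_data(gts, "mtDNA")
  expect_true(all(d_f$total < d_all$total))
  expect_equal(sum(d_f$total),
               sum(!is.na(gts$mito[gts$sex == "F"])))
})
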